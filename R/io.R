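#' Read and write velocity-field series
#'
#' CSV with columns `frame`, `t_h`, `x_um`, `y_um`, `u_umph`, `v_umph`;
#' units are micrometers, hours and micrometers per hour throughout.
#' Malformed rows (non-finite velocities, missing coordinates) are rejected
#' with their line numbers.
#'
#' @param fields A velocity-field tibble.
#' @param path File path.
#' @return `read_field_series()` returns the validated tibble;
#'   `write_field_series()` returns `path` invisibly.
#' @export
write_field_series <- function(fields, path) {
  check_columns(fields, c("frame", "t_h", "x_um", "y_um", "u_umph", "v_umph"))
  readr::write_csv(fields[c("frame", "t_h", "x_um", "y_um", "u_umph", "v_umph")],
                   path, progress = FALSE)
  invisible(path)
}

#' @rdname write_field_series
#' @export
read_field_series <- function(path) {
  tbl <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  check_columns(tbl, c("frame", "t_h", "x_um", "y_um", "u_umph", "v_umph"), path)
  bad <- which(!is.finite(tbl$u_umph) | !is.finite(tbl$v_umph) |
                 !is.finite(tbl$x_um) | !is.finite(tbl$y_um))
  if (length(bad)) {
    abort(sprintf("%s: malformed rows at lines %s", path,
                  paste(head(bad + 1L, 5), collapse = ", ")))
  }
  check_monotone_frames(tbl$frame, path)
  tbl
}

#' Read and write trajectory tables
#'
#' CSV with columns `track_id`, `frame`, `x_um`, `y_um`. The frame interval
#' (hours) is stored as a `# frame_interval_h:` comment header and restored
#' into the `frame_interval_h` attribute on read.
#'
#' @param trajectories A trajectory tibble.
#' @param path File path.
#' @param frame_interval_h Frame interval in hours (defaults to the
#'   attribute on `trajectories`).
#' @return `read_trajectories()` returns the tibble with the attribute set.
#' @export
write_trajectories <- function(trajectories, path, frame_interval_h = NULL) {
  check_columns(trajectories, c("track_id", "frame", "x_um", "y_um"))
  frame_interval_h <- frame_interval_h %||% attr(trajectories, "frame_interval_h")
  if (!is.null(frame_interval_h)) {
    writeLines(sprintf("# frame_interval_h: %.17g", frame_interval_h), path)
    readr::write_csv(trajectories[c("track_id", "frame", "x_um", "y_um")], path,
                     append = TRUE, col_names = TRUE, progress = FALSE)
  } else {
    readr::write_csv(trajectories[c("track_id", "frame", "x_um", "y_um")], path,
                     progress = FALSE)
  }
  invisible(path)
}

#' @rdname write_trajectories
#' @export
read_trajectories <- function(path) {
  first <- readLines(path, n = 1)
  interval <- NULL
  if (grepl("^# frame_interval_h:", first)) {
    interval <- as.double(sub("^# frame_interval_h:\\s*", "", first))
  }
  tbl <- readr::read_csv(path, comment = "#", show_col_types = FALSE,
                         progress = FALSE)
  check_columns(tbl, c("track_id", "frame", "x_um", "y_um"), path)
  bad <- which(!is.finite(tbl$x_um) | !is.finite(tbl$y_um))
  if (length(bad)) {
    abort(sprintf("%s: non-finite positions at data rows %s", path,
                  paste(head(bad, 5), collapse = ", ")))
  }
  incr <- dplyr::summarise(dplyr::group_by(tbl, .data$track_id),
                           ok = !is.unsorted(.data$frame, strictly = TRUE),
                           .groups = "drop")
  if (!all(incr$ok)) {
    abort(sprintf("%s: frames not strictly increasing for tracks %s", path,
                  paste(head(incr$track_id[!incr$ok], 5), collapse = ", ")))
  }
  attr(tbl, "frame_interval_h") <- interval
  tbl
}

#' Read and write defect tables
#'
#' CSV with columns `frame`, `t_h`, `x_um`, `y_um`, `charge`,
#' `cluster_size`. Rows with charge 0 violate the defect invariant and are
#' rejected.
#'
#' @param defects A defect tibble.
#' @param path File path.
#' @export
write_defects <- function(defects, path) {
  check_columns(defects, c("frame", "t_h", "x_um", "y_um", "charge", "cluster_size"))
  readr::write_csv(defects[c("frame", "t_h", "x_um", "y_um", "charge",
                             "cluster_size")], path, progress = FALSE)
  invisible(path)
}

#' @rdname write_defects
#' @export
read_defects <- function(path) {
  tbl <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  check_columns(tbl, c("frame", "t_h", "x_um", "y_um", "charge", "cluster_size"),
                path)
  bad <- which(tbl$charge == 0 | !is.finite(tbl$charge))
  if (length(bad)) {
    abort(sprintf("%s: zero/invalid charge at lines %s", path,
                  paste(head(bad + 1L, 5), collapse = ", ")))
  }
  check_monotone_frames(tbl$frame, path)
  tbl
}

check_columns <- function(tbl, cols, path = NULL) {
  miss <- setdiff(cols, names(tbl))
  if (length(miss)) {
    where <- if (is.null(path)) "" else paste0(path, ": ")
    abort(sprintf("%smissing columns: %s", where, paste(miss, collapse = ", ")))
  }
  invisible(tbl)
}

check_monotone_frames <- function(frame, path) {
  if (is.unsorted(frame)) {
    abort(sprintf("%s: frame indices are not monotone non-decreasing", path))
  }
}

#' Assemble a full pipeline configuration
#'
#' Collects every knob of the simulate -> grid -> detect -> track -> metrics
#' pipeline, with all defaults explicit so the configuration round-trips
#' losslessly through YAML ([write_run_config()] / [read_run_config()]).
#'
#' @param n,d Lattice size and mean spacing (see [lattice_spec()]).
#' @param domain_radius Confinement radius, um.
#' @param k_tilde,gamma_tilde,b_tilde,v_c,dt Model parameters
#'   (see [sim_params()]).
#' @param duration,snapshot_every Simulated hours and snapshot interval.
#' @param grid_spacing,window PIV-like sampling (see
#'   [grid_particle_velocities()]).
#' @param merge_radius,min_persistence_frames,link_radius Detection
#'   parameters (see [detection_params()]).
#' @param event_radius,border_margin Event-calling parameters.
#' @param seed Master seed; all pipeline stages derive their seeds from it.
#' @return A list with class `run_config`.
#' @export
run_config <- function(n = 2000, d = 22.5,
                       domain_radius = default_domain_radius(n, d),
                       k_tilde = 40, gamma_tilde = 1.5, b_tilde = k_tilde / 4,
                       v_c = 35, dt = NULL, duration = 24,
                       snapshot_every = 0.25, grid_spacing = 66, window = 165,
                       merge_radius = 165, min_persistence_frames = 2,
                       link_radius = merge_radius, event_radius = 165,
                       border_margin = 165, seed = 1L) {
  cfg <- list(n = as.integer(n), d = d, domain_radius = domain_radius,
              k_tilde = k_tilde, gamma_tilde = gamma_tilde, b_tilde = b_tilde,
              v_c = v_c, dt = dt, duration = duration,
              snapshot_every = snapshot_every, grid_spacing = grid_spacing,
              window = window, merge_radius = merge_radius,
              min_persistence_frames = as.integer(min_persistence_frames),
              link_radius = link_radius, event_radius = event_radius,
              border_margin = border_margin, seed = as.integer(seed))
  structure(cfg, class = "run_config")
}

#' @rdname run_config
#' @param config A `run_config`.
#' @param path YAML file path.
#' @export
write_run_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path, precision = 15)
  invisible(path)
}

#' @rdname run_config
#' @export
read_run_config <- function(path) {
  raw <- yaml::read_yaml(path)
  do.call(run_config, raw[!vapply(raw, is.null, logical(1))])
}

# djb2-style digest of the canonical YAML text; recorded in pipeline outputs
# so a result can be traced back to its exact configuration
config_hash <- function(config) {
  txt <- yaml::as.yaml(unclass(config), precision = 15)
  bytes <- utf8ToInt(txt)
  h <- 5381
  for (b in bytes) h <- (h * 33 + b) %% 2147483647
  sprintf("%08x", h)
}

#' Run the full simulation-and-analysis pipeline
#'
#' Builds the lattice, integrates the active elastic solid, grids particle
#' velocities PIV-style, detects and tracks defects, calls annihilation and
#' proliferation events, and computes the order-metric time series
#' (defect counts, mean speed, correlation length). Deterministic for a
#' fixed config seed.
#'
#' @param config A [run_config()].
#' @param out_dir Optional output directory; when given, writes
#'   `fields.csv`, `defects.csv`, `tracks.csv`, `events.csv`, `metrics.csv`,
#'   `config.yaml` and `log.txt`.
#' @param keep_fields Keep the (possibly large) field series in the returned
#'   object (default `TRUE`).
#' @return A list with class `pipeline_result`: `network`, `run`, `fields`,
#'   `defects`, `tracks`, `events`, `metrics`, `meta`.
#' @export
run_pipeline <- function(config = run_config(), out_dir = NULL,
                         keep_fields = TRUE) {
  stopifnot(inherits(config, "run_config"))
  spec <- lattice_spec(n = config$n, d = config$d,
                       domain_radius = config$domain_radius,
                       seed = config$seed)
  net <- build_network(pack_disks(spec), spec)
  params <- sim_params(v_c = config$v_c, k_tilde = config$k_tilde,
                       gamma_tilde = config$gamma_tilde,
                       b_tilde = config$b_tilde, d = config$d,
                       dt = config$dt %||% NULL, seed = config$seed + 1L)
  run <- simulate_aes(net, params, duration = config$duration,
                      snapshot_every = config$snapshot_every, confine = TRUE)
  R <- config$domain_radius
  half_n <- ceiling(R / config$grid_spacing)
  grid <- field_grid(2 * half_n + 1, 2 * half_n + 1, config$grid_spacing,
                     origin = c(-half_n * config$grid_spacing,
                                -half_n * config$grid_spacing))
  fields <- dplyr::bind_rows(lapply(split_frames(run$snapshots), function(sn) {
    grid_particle_velocities(sn, spacing = config$grid_spacing,
                             window = config$window, grid = grid,
                             frame = sn$frame[1], t_h = sn$t_h[1])
  }))
  dpar <- detection_params(merge_radius = config$merge_radius,
                           min_persistence_frames = config$min_persistence_frames,
                           link_radius = config$link_radius)
  defects <- detect_defects(fields, dpar)
  tracks <- link_defect_tracks(defects, link_radius = config$link_radius)
  bounds <- c(-R, R, -R, R)
  events <- call_events(tracks, event_radius = config$event_radius,
                        bounds = bounds, border_margin = config$border_margin)
  dens <- density_series(defects, domain_area_um2 = pi * R^2)
  per_frame <- lapply(split_frames(fields), function(fr) {
    xi <- correlation_length(correlation_function(fr))
    tibble::tibble(frame = fr$frame[1], nu_umph = mean_speed(fr),
                   xi_um = xi$xi_um, xi_censored = xi$censored)
  })
  metrics <- dplyr::left_join(dens, dplyr::bind_rows(per_frame), by = "frame")
  meta <- list(config = config, hash = config_hash(config),
               k_tilde = params$k_tilde, gamma_tilde = params$gamma_tilde,
               dt = params$dt, seed = config$seed,
               package_version = as.character(utils::packageVersion("defectflow")))
  res <- structure(
    list(network = net, run = run, fields = if (keep_fields) fields,
         defects = defects, tracks = tracks, events = events,
         metrics = metrics, meta = meta),
    class = "pipeline_result")
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_field_series(fields, file.path(out_dir, "fields.csv"))
    write_defects(defects, file.path(out_dir, "defects.csv"))
    readr::write_csv(tracks, file.path(out_dir, "tracks.csv"), progress = FALSE)
    readr::write_csv(events, file.path(out_dir, "events.csv"), progress = FALSE)
    readr::write_csv(metrics, file.path(out_dir, "metrics.csv"), progress = FALSE)
    write_run_config(config, file.path(out_dir, "config.yaml"))
    writeLines(c(
      sprintf("defectflow %s", meta$package_version),
      sprintf("config_hash %s", meta$hash),
      sprintf("seed %d", meta$seed),
      sprintf("k_tilde %.6g gamma_tilde %.6g dt %.6g h",
              meta$k_tilde, meta$gamma_tilde, meta$dt)
    ), file.path(out_dir, "log.txt"))
  }
  res
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat(sprintf("<pipeline_result> N = %d, %d frames, %d defect records, %d events (hash %s)\n",
              nrow(x$network$points), nrow(attr(x$defects, "frames") %||% x$metrics),
              nrow(x$defects), nrow(x$events), x$meta$hash))
  invisible(x)
}
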