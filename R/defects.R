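#' Detection parameters for topological defects
#'
#' @param merge_radius Same-charge detections closer than this are merged
#'   into a single defect (um; default 165).
#' @param min_persistence_frames Keep only defects corroborated in at least
#'   this many consecutive frames (default 2).
#' @param link_radius Matching radius used by the persistence filter (um;
#'   defaults to `merge_radius`).
#' @return A list with class `detection_params`.
#' @export
detection_params <- function(merge_radius = 165, min_persistence_frames = 2,
                             link_radius = merge_radius) {
  stopifnot(merge_radius > 0, min_persistence_frames >= 1, link_radius > 0)
  structure(list(merge_radius = merge_radius,
                 min_persistence_frames = as.integer(min_persistence_frames),
                 link_radius = link_radius),
            class = "detection_params")
}

# Winding numbers at every grid node with all 8 neighbors valid.
# theta_k = atan2(v, u) at the 8 neighbors traversed anticlockwise starting
# at the top-left; alpha_k lifts theta to [0, 2pi); consecutive differences
# are range-adjusted to (-pi, pi] and summed.
winding_matrix <- function(field) {
  fm <- field_matrices(field)
  nx <- fm$grid$nx; ny <- fm$grid$ny
  theta <- atan2(fm$v, fm$u)
  alpha <- ifelse(theta < 0, theta + 2 * pi, theta)
  core_x <- 2:(nx - 1); core_y <- 2:(ny - 1)
  # anticlockwise loop in mathematical axes (x right, y up)
  offs <- list(c(-1, 1), c(-1, 0), c(-1, -1), c(0, -1),
               c(1, -1), c(1, 0), c(1, 1), c(0, 1))
  a <- lapply(offs, function(o) alpha[core_x + o[1], core_y + o[2], drop = FALSE])
  ok <- Reduce(`&`, lapply(offs, function(o)
    fm$valid[core_x + o[1], core_y + o[2], drop = FALSE]))
  total <- 0
  for (k in 1:8) {
    prev <- if (k == 1) a[[8]] else a[[k - 1]]
    d <- a[[k]] - prev
    d <- d + 2 * pi * (d < -pi) - 2 * pi * (d > pi)
    total <- total + d
  }
  w <- matrix(NA_real_, nx, ny)
  core <- round(total / (2 * pi))
  core[!ok] <- NA_real_
  w[core_x, core_y] <- core
  list(w = w, grid = fm$grid)
}

#' Winding number at one grid node
#'
#' Computes the local winding number of the velocity direction around node
#' `(i, j)` (x and y grid indices, 1-based) from its eight neighbors,
#' traversed anticlockwise starting at the top-left neighbor. Returns `NA`
#' if any neighbor is invalid or outside the grid.
#'
#' @param field A velocity-field tibble (one frame).
#' @param i,j Grid indices along x and y.
#' @return Integer winding number (`+1` vortex, `-1` saddle, `0` regular).
#' @export
winding_number <- function(field, i, j) {
  wm <- winding_matrix(field)
  if (i < 1 || i > wm$grid$nx || j < 1 || j > wm$grid$ny) {
    abort("grid indices out of range")
  }
  wm$w[i, j]
}

# single-linkage clusters among points within `radius` (returns labels)
single_linkage <- function(x, y, radius) {
  n <- length(x)
  if (n <= 1) return(rep(1L, n))
  adj <- as.matrix(stats::dist(cbind(x, y))) < radius
  comp <- seq_len(n)
  repeat {
    new <- apply(adj, 1, function(row) min(comp[row]))
    if (all(new == comp)) break
    comp <- new
  }
  match(comp, unique(comp))
}

#' Detect topological defects in one velocity-field frame
#'
#' Flags every grid node whose winding number is nonzero, then merges
#' same-charge detections closer than `merge_radius` by single-linkage
#' clustering; each cluster is reported at the centroid of its member
#' nodes. Charges of magnitude larger than one (possible on pathological
#' fields) are reported verbatim.
#'
#' @param field A velocity-field tibble (one frame).
#' @param params A [detection_params()].
#' @return A tibble with columns `frame`, `t_h`, `x_um`, `y_um`, `charge`,
#'   `cluster_size` (possibly empty).
#' @export
detect_frame <- function(field, params = detection_params()) {
  wm <- winding_matrix(field)
  idx <- which(!is.na(wm$w) & wm$w != 0, arr.ind = TRUE)
  fr <- field$frame[1] %||% 1L
  th <- field$t_h[1] %||% 0
  if (nrow(idx) == 0) return(empty_defects())
  pts <- tibble::tibble(
    x_um = wm$grid$xs[idx[, 1]],
    y_um = wm$grid$ys[idx[, 2]],
    charge = wm$w[idx]
  )
  out <- lapply(split(pts, pts$charge), function(g) {
    lab <- single_linkage(g$x_um, g$y_um, params$merge_radius)
    dplyr::summarise(dplyr::group_by(g, cluster = lab),
                     x_um = mean(.data$x_um), y_um = mean(.data$y_um),
                     charge = .data$charge[1], cluster_size = dplyr::n(),
                     .groups = "drop")
  })
  res <- dplyr::bind_rows(out)
  tibble::tibble(frame = as.integer(fr), t_h = as.double(th),
                 x_um = res$x_um, y_um = res$y_um,
                 charge = as.integer(res$charge),
                 cluster_size = as.integer(res$cluster_size))
}

empty_defects <- function() {
  tibble::tibble(frame = integer(), t_h = double(), x_um = double(),
                 y_um = double(), charge = integer(), cluster_size = integer())
}

#' Detect defects across a velocity-field series
#'
#' Runs [detect_frame()] on every frame and, when `params$min_persistence_frames > 1`,
#' applies the persistence filter of [filter_persistent()].
#'
#' @param fields A multi-frame velocity-field tibble.
#' @param params A [detection_params()].
#' @param persist Apply the persistence filter (default `TRUE`).
#' @return A defect tibble with attribute `frames` (tibble `frame`, `t_h` of
#'   all analyzed frames, for downstream time series).
#' @export
detect_defects <- function(fields, params = detection_params(), persist = TRUE) {
  frames <- split_frames(fields)
  dets <- dplyr::bind_rows(lapply(frames, detect_frame, params = params))
  meta <- tibble::tibble(
    frame = vapply(frames, function(f) as.integer(f$frame[1]), integer(1)),
    t_h = vapply(frames, function(f) as.double(f$t_h[1] %||% 0), double(1))
  )
  if (persist && params$min_persistence_frames > 1) {
    dets <- filter_persistent(dets, params, all_frames = meta$frame)
  }
  attr(dets, "frames") <- meta
  dets
}

#' Keep only defects that persist across consecutive frames
#'
#' A detection is kept when it belongs to a chain of same-charge detections
#' in consecutive frames (each within `link_radius` of the previous) whose
#' length is at least `min_persistence_frames`.
#'
#' @param defects A defect tibble (from [detect_frame()] calls).
#' @param params A [detection_params()].
#' @param all_frames Integer vector of analyzed frames (defaults to the
#'   range seen in `defects`); consecutive means adjacent in this vector.
#' @return The filtered defect tibble.
#' @export
filter_persistent <- function(defects, params = detection_params(),
                              all_frames = NULL) {
  if (nrow(defects) == 0) return(defects)
  if (is.null(all_frames)) {
    all_frames <- attr(defects, "frames")$frame %||% sort(unique(defects$frame))
  }
  all_frames <- sort(unique(all_frames))
  per <- lapply(all_frames, function(f) defects[defects$frame == f, , drop = FALSE])
  nfr <- length(per)
  fwd <- lapply(per, function(d) rep(1L, nrow(d)))
  for (t in rev(seq_len(nfr - 1))) {
    fwd[[t]] <- 1L + chain_extent(per[[t]], per[[t + 1]], fwd[[t + 1]],
                                  params$link_radius)
  }
  bwd <- lapply(per, function(d) rep(1L, nrow(d)))
  for (t in 2:max(nfr, 2)) {
    if (t > nfr) break
    bwd[[t]] <- 1L + chain_extent(per[[t]], per[[t - 1]], bwd[[t - 1]],
                                  params$link_radius)
  }
  keep <- unlist(lapply(seq_len(nfr), function(t) {
    if (nrow(per[[t]]) == 0) return(logical(0))
    fwd[[t]] + bwd[[t]] - 1L >= params$min_persistence_frames
  }))
  out <- dplyr::bind_rows(per)[keep, , drop = FALSE]
  attr(out, "frames") <- attr(defects, "frames")
  out
}

# for each record in `cur`, the best chain length among same-charge records
# of the adjacent frame within `radius` (0 if none)
chain_extent <- function(cur, adjacent, adj_len, radius) {
  if (nrow(cur) == 0) return(integer(0))
  vapply(seq_len(nrow(cur)), function(r) {
    if (nrow(adjacent) == 0) return(0L)
    same <- adjacent$charge == cur$charge[r]
    if (!any(same)) return(0L)
    d <- sqrt((adjacent$x_um[same] - cur$x_um[r])^2 +
              (adjacent$y_um[same] - cur$y_um[r])^2)
    near <- d <= radius
    if (!any(near)) return(0L)
    max(adj_len[same][near])
  }, integer(1))
}

#' Defect counts and densities over time
#'
#' @param defects A defect tibble from [detect_defects()].
#' @param domain_area_um2 Observed area in square micrometers.
#' @param frames Optional tibble (`frame`, `t_h`) of all analyzed frames;
#'   defaults to the `frames` attribute of `defects`.
#' @return A tibble with `frame`, `t_h`, `n_plus`, `n_minus`, `n_total`,
#'   and densities per mm^2.
#' @export
density_series <- function(defects, domain_area_um2, frames = NULL) {
  stopifnot(domain_area_um2 > 0)
  frames <- frames %||% attr(defects, "frames")
  if (is.null(frames)) {
    frames <- tibble::tibble(frame = sort(unique(defects$frame)), t_h = NA_real_)
  }
  mm2 <- domain_area_um2 / 1e6
  counts <- dplyr::summarise(
    dplyr::group_by(defects, .data$frame),
    n_plus = sum(.data$charge > 0), n_minus = sum(.data$charge < 0),
    .groups = "drop")
  out <- dplyr::left_join(frames, counts, by = "frame")
  out$n_plus[is.na(out$n_plus)] <- 0L
  out$n_minus[is.na(out$n_minus)] <- 0L
  dplyr::mutate(out,
                n_total = .data$n_plus + .data$n_minus,
                dens_plus_mm2 = .data$n_plus / mm2,
                dens_minus_mm2 = .data$n_minus / mm2,
                dens_total_mm2 = .data$n_total / mm2)
}
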