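#' Link per-frame defects into tracks
#'
#' Charge-respecting greedy mutual-nearest-neighbor linking between
#' successive analyzed frames: a detection in frame t and one in frame t+1
#' are linked when each is the other's nearest same-charge neighbor and
#' their separation is below `link_radius`. Unmatched detections start or
#' end tracks; gap closing is disabled (the persistence filter already
#' smooths single-frame dropouts).
#'
#' @param defects A defect tibble from [detect_defects()].
#' @param link_radius Maximum link distance in um (default 165).
#' @return A tibble `track_id`, `charge`, `frame`, `t_h`, `x_um`, `y_um`,
#'   ordered by track and frame; carries over the `frames` attribute.
#' @export
link_defect_tracks <- function(defects, link_radius = 165) {
  if (nrow(defects) == 0) {
    return(tibble::tibble(track_id = integer(), charge = integer(),
                          frame = integer(), t_h = double(),
                          x_um = double(), y_um = double()))
  }
  frames <- sort(unique(defects$frame))
  per <- lapply(frames, function(f) defects[defects$frame == f, , drop = FALSE])
  ids <- vector("list", length(per))
  next_id <- 0L
  ids[[1]] <- seq_len(nrow(per[[1]])) + next_id
  next_id <- next_id + nrow(per[[1]])
  for (t in seq_len(length(per) - 1)) {
    cur <- per[[t]]; nxt <- per[[t + 1]]
    match_next <- rep(NA_integer_, nrow(nxt))
    if (nrow(cur) > 0 && nrow(nxt) > 0) {
      d <- outer(seq_len(nrow(cur)), seq_len(nrow(nxt)), function(a, b) {
        sqrt((cur$x_um[a] - nxt$x_um[b])^2 + (cur$y_um[a] - nxt$y_um[b])^2)
      })
      d[outer(cur$charge, nxt$charge, `!=`)] <- Inf
      d[d > link_radius] <- Inf
      if (any(is.finite(d))) {
        best_fwd <- apply(d, 1, which.min)   # cur -> nxt
        best_bwd <- apply(d, 2, which.min)   # nxt -> cur
        for (a in seq_len(nrow(cur))) {
          b <- best_fwd[a]
          if (is.finite(d[a, b]) && best_bwd[b] == a) match_next[b] <- a
        }
      }
    }
    new_ids <- integer(nrow(nxt))
    linked <- !is.na(match_next)
    new_ids[linked] <- ids[[t]][match_next[linked]]
    n_new <- sum(!linked)
    if (n_new > 0) {
      new_ids[!linked] <- next_id + seq_len(n_new)
      next_id <- next_id + n_new
    }
    ids[[t + 1]] <- new_ids
  }
  out <- dplyr::bind_rows(per)
  out$track_id <- unlist(ids)
  out <- dplyr::arrange(
    dplyr::select(out, "track_id", "charge", "frame", "t_h", "x_um", "y_um"),
    .data$track_id, .data$frame)
  attr(out, "frames") <- attr(defects, "frames")
  out
}

#' Per-track defect velocities
#'
#' Defect speed is the Euclidean path length of a track divided by its
#' number of time points, converted to um/h with the frame interval. Only
#' stable tracks with at least `min_length` consecutive time points are
#' reported.
#'
#' @param tracks A track tibble from [link_defect_tracks()].
#' @param frame_interval_h Frame interval in hours; by default inferred from
#'   the `t_h` column.
#' @param min_length Minimum number of time points per track (default 25).
#' @return A tibble `track_id`, `charge`, `n_points`, `path_um`,
#'   `velocity_umph`.
#' @export
track_velocities <- function(tracks, frame_interval_h = NULL, min_length = 25) {
  if (is.null(frame_interval_h)) {
    dt <- diff(sort(unique(tracks$t_h))) # nolint
    if (!length(dt) || !all(is.finite(dt))) {
      abort("cannot infer `frame_interval_h` from `t_h`; supply it")
    }
    frame_interval_h <- stats::median(dt)
  }
  stopifnot(frame_interval_h > 0)
  per <- split(tracks, tracks$track_id)
  res <- lapply(per, function(tr) {
    tr <- tr[order(tr$frame), ]
    path <- sum(sqrt(diff(tr$x_um)^2 + diff(tr$y_um)^2))
    tibble::tibble(track_id = tr$track_id[1], charge = tr$charge[1],
                   n_points = nrow(tr), path_um = path,
                   velocity_umph = path / nrow(tr) / frame_interval_h)
  })
  out <- dplyr::bind_rows(res)
  out[out$n_points >= min_length, , drop = FALSE]
}

#' Call annihilation and proliferation events
#'
#' An annihilation is a (+1, -1) track pair whose last observations fall
#' within `event_frame_window` frames of each other and within
#' `event_radius`; a proliferation is the symmetric condition on first
#' observations. Tracks that end in the last analyzed frame (or begin in the
#' first) are not deaths (births), and endpoints within `border_margin` of
#' the field bounds are excluded, so leaving the field of view is not
#' mistaken for annihilation.
#'
#' Annihilation of a vortex-antivortex pair is preceded by mutual
#' attraction; with `require_convergence = TRUE` (default) an annihilation
#' is only called when the pair coexisted for at least `convergence_frames`
#' frames and its separation shrank over that approach, and a proliferation
#' only when the newborn pair moved apart symmetrically. This separates
#' genuine pair events from detections that merely co-appear and co-vanish
#' while local order first condenses out of the disordered field.
#'
#' @param tracks A track tibble from [link_defect_tracks()].
#' @param event_radius Maximum endpoint separation in um (default 165).
#' @param event_frame_window Maximum frame offset between the two endpoints
#'   (default 1).
#' @param bounds Optional field bounds `c(xmin, xmax, ymin, ymax)` in um for
#'   border exclusion.
#' @param border_margin Width of the excluded border strip in um
#'   (default 165, one interrogation window).
#' @param require_convergence Demand mutual approach before annihilation
#'   (recession after proliferation); see Details.
#' @param convergence_frames Number of coexistence frames over which the
#'   approach/recession is assessed (default 3).
#' @return A tibble `type`, `frame`, `t_h`, `x_um`, `y_um`, `plus_track`,
#'   `minus_track`, `separation_um`.
#' @export
call_events <- function(tracks, event_radius = 165, event_frame_window = 1,
                        bounds = NULL, border_margin = 165,
                        require_convergence = TRUE, convergence_frames = 3) {
  empty <- tibble::tibble(type = character(), frame = integer(),
                          t_h = double(), x_um = double(), y_um = double(),
                          plus_track = integer(), minus_track = integer(),
                          separation_um = double())
  if (nrow(tracks) == 0) return(empty)
  frames <- attr(tracks, "frames")$frame %||% sort(unique(tracks$frame))
  first_f <- min(frames); last_f <- max(frames)
  ends <- dplyr::summarise(
    dplyr::group_by(tracks, .data$track_id),
    charge = .data$charge[1],
    birth = min(.data$frame), death = max(.data$frame),
    x_birth = .data$x_um[which.min(.data$frame)],
    y_birth = .data$y_um[which.min(.data$frame)],
    x_death = .data$x_um[which.max(.data$frame)],
    y_death = .data$y_um[which.max(.data$frame)],
    t_death = .data$t_h[which.max(.data$frame)],
    t_birth = .data$t_h[which.min(.data$frame)],
    .groups = "drop")
  in_border <- function(x, y) {
    if (is.null(bounds)) return(rep(FALSE, length(x)))
    x < bounds[1] + border_margin | x > bounds[2] - border_margin |
      y < bounds[3] + border_margin | y > bounds[4] - border_margin
  }
  pair_events <- function(cand, fcol, xcol, ycol, tcol, type) {
    plus <- cand[cand$charge > 0, , drop = FALSE]
    minus <- cand[cand$charge < 0, , drop = FALSE]
    if (nrow(plus) == 0 || nrow(minus) == 0) return(empty)
    combos <- expand.grid(p = seq_len(nrow(plus)), m = seq_len(nrow(minus)))
    dx <- plus[[xcol]][combos$p] - minus[[xcol]][combos$m]
    dy <- plus[[ycol]][combos$p] - minus[[ycol]][combos$m]
    df <- abs(plus[[fcol]][combos$p] - minus[[fcol]][combos$m])
    sep <- sqrt(dx^2 + dy^2)
    ok <- sep <= event_radius & df <= event_frame_window
    combos <- combos[ok, , drop = FALSE]; sep <- sep[ok]
    if (!nrow(combos)) return(empty)
    ord <- order(sep)
    used_p <- logical(nrow(plus)); used_m <- logical(nrow(minus))
    rows <- list()
    for (r in ord) {
      p <- combos$p[r]; m <- combos$m[r]
      if (used_p[p] || used_m[m]) next
      if (require_convergence &&
          !pair_converges(tracks, plus$track_id[p], minus$track_id[m],
                          type, convergence_frames)) next
      used_p[p] <- TRUE; used_m[m] <- TRUE
      rows[[length(rows) + 1]] <- tibble::tibble(
        type = type,
        frame = as.integer(max(plus[[fcol]][p], minus[[fcol]][m])),
        t_h = max(plus[[tcol]][p], minus[[tcol]][m]),
        x_um = (plus[[xcol]][p] + minus[[xcol]][m]) / 2,
        y_um = (plus[[ycol]][p] + minus[[ycol]][m]) / 2,
        plus_track = as.integer(plus$track_id[p]),
        minus_track = as.integer(minus$track_id[m]),
        separation_um = sep[r])
    }
    if (length(rows) == 0) empty else dplyr::bind_rows(rows)
  }
  dying <- ends[ends$death < last_f & !in_border(ends$x_death, ends$y_death), ]
  born <- ends[ends$birth > first_f & !in_border(ends$x_birth, ends$y_birth), ]
  ann <- pair_events(dying, "death", "x_death", "y_death", "t_death", "annihilation")
  pro <- pair_events(born, "birth", "x_birth", "y_birth", "t_birth", "proliferation")
  dplyr::bind_rows(ann, pro)
}

# Separation history of a (+1, -1) track pair over their common frames;
# TRUE when the pair approaches into an annihilation (or recedes from a
# proliferation) over `k` coexistence frames.
pair_converges <- function(tracks, plus_id, minus_id, type, k) {
  a <- tracks[tracks$track_id == plus_id, ]
  b <- tracks[tracks$track_id == minus_id, ]
  common <- intersect(a$frame, b$frame)
  if (length(common) < k) return(FALSE)
  common <- sort(common)
  sep <- sqrt((a$x_um[match(common, a$frame)] - b$x_um[match(common, b$frame)])^2 +
              (a$y_um[match(common, a$frame)] - b$y_um[match(common, b$frame)])^2)
  if (type == "annihilation") {
    tail(sep, 1) < sep[length(sep) - k + 1]
  } else {
    sep[1] < sep[k]
  }
}

#' Flow-direction reversal across an annihilation
#'
#' After a vortex-antivortex pair annihilates, the directed migration in the
#' corridor between the two defects reverses. This measures the circular-mean
#' velocity direction in the rectangle spanned by the pair's final positions,
#' one frame before the pair disappears versus `after_frames` frames later,
#' and returns the absolute angular change in degrees.
#'
#' @param event One row of the [call_events()] table with
#'   `type == "annihilation"`.
#' @param tracks The track tibble the event was called from.
#' @param fields The velocity-field series.
#' @param corridor_halfwidth Half-width of the corridor rectangle, um
#'   (default 82.5).
#' @param after_frames Frames after disappearance at which the "after"
#'   direction is read (default 1).
#' @return Absolute angular change in degrees, in `[0, 180]`.
#' @export
reversal_angle <- function(event, tracks, fields, corridor_halfwidth = 82.5,
                           after_frames = 1) {
  if (!identical(event$type, "annihilation")) {
    abort("`event` must be an annihilation event")
  }
  pe <- tracks[tracks$track_id == event$plus_track, ]
  me <- tracks[tracks$track_id == event$minus_track, ]
  a <- c(pe$x_um[which.max(pe$frame)], pe$y_um[which.max(pe$frame)])
  b <- c(me$x_um[which.max(me$frame)], me$y_um[which.max(me$frame)])
  death <- event$frame
  frames <- sort(unique(fields$frame))
  after <- frames[frames > death]
  if (length(after) < after_frames) {
    abort("not enough frames after the event to measure the reversal")
  }
  f_before <- fields[fields$frame == death, , drop = FALSE]
  f_after <- fields[fields$frame == after[after_frames], , drop = FALSE]
  th1 <- corridor_direction(f_before, a, b, corridor_halfwidth)
  th2 <- corridor_direction(f_after, a, b, corridor_halfwidth)
  if (is.na(th1) || is.na(th2)) abort("empty corridor in the velocity field")
  d <- abs((th2 - th1 + pi) %% (2 * pi) - pi)
  d * 180 / pi
}

# circular-mean flow direction among field nodes inside the rectangle
# between points a and b
corridor_direction <- function(field, a, b, halfwidth) {
  ab <- b - a
  len <- sqrt(sum(ab^2))
  if (len == 0) return(NA_real_)
  e <- ab / len
  px <- field$x_um - a[1]; py <- field$y_um - a[2]
  along <- px * e[1] + py * e[2]
  across <- -px * e[2] + py * e[1]
  sel <- along >= 0 & along <= len & abs(across) <= halfwidth
  if (!any(sel)) return(NA_real_)
  th <- atan2(field$v_umph[sel], field$u_umph[sel])
  atan2(mean(sin(th)), mean(cos(th)))
}

#' Proliferation-to-annihilation event chains (partner exchange)
#'
#' Reports, descriptively, pairs of events where a proliferation is later
#' followed by an annihilation that shares at least one participating track:
#' the signature of defect partner exchange during polarity flipping.
#'
#' @param events An event tibble from [call_events()].
#' @return A tibble with one row per chained (proliferation, annihilation)
#'   pair and the shared track ids.
#' @export
event_chains <- function(events) {
  pro <- events[events$type == "proliferation", , drop = FALSE]
  ann <- events[events$type == "annihilation", , drop = FALSE]
  if (nrow(pro) == 0 || nrow(ann) == 0) {
    return(tibble::tibble(pro_frame = integer(), ann_frame = integer(),
                          shared_plus = logical(), shared_minus = logical()))
  }
  combos <- expand.grid(p = seq_len(nrow(pro)), a = seq_len(nrow(ann)))
  sp <- pro$plus_track[combos$p] == ann$plus_track[combos$a]
  sm <- pro$minus_track[combos$p] == ann$minus_track[combos$a]
  ok <- (sp | sm) & pro$frame[combos$p] < ann$frame[combos$a]
  tibble::tibble(pro_frame = pro$frame[combos$p[ok]],
                 ann_frame = ann$frame[combos$a[ok]],
                 shared_plus = sp[ok], shared_minus = sm[ok])
}

#' Harvest reversal angles across isolated pair annihilations
#'
#' Convenience wrapper for the annihilation-reversal analysis: takes the
#' tracks/events/fields trio of a [run_pipeline()] result, keeps
#' annihilation events for which the inter-defect corridor is well defined,
#' and returns the corridor direction change of each in degrees.
#'
#' Two validity conditions are applied. Isolation: no third defect within
#' `isolation_radius` of the event at the death frame (a neighboring defect
#' distorts the corridor). Dipole signature: for an ideal vortex-antivortex
#' pair the direction field between the defects is anti-parallel to the
#' surrounding flow regardless of the spin phase (superposing
#' `theta = phi_+ - phi_- + psi` gives `psi - pi` on the joining segment
#' versus `psi` far away), so events whose corridor is not anti-aligned
#' (> 90 degrees) with the ambient annulus are winding detections inside
#' unresolved turbulent texture, not genuine pair annihilations, and are
#' dropped.
#'
#' @param tracks,events,fields Components as produced by the pipeline.
#' @param isolation_radius Exclusion radius for third defects, um
#'   (default 330, twice the event radius).
#' @param ambient_annulus Radii (um) of the annulus around the event used
#'   for the ambient flow direction (default `c(165, 400)`).
#' @param dipole_check Apply the anti-alignment signature (default `TRUE`).
#' @param corridor_halfwidth,after_frames Passed to [reversal_angle()].
#' @return A tibble `frame`, `t_h`, `x_um`, `y_um`, `separation_um`,
#'   `reversal_deg` (one row per isolated annihilation).
#' @export
annihilation_reversals <- function(tracks, events, fields,
                                   isolation_radius = 330,
                                   ambient_annulus = c(165, 400),
                                   dipole_check = TRUE,
                                   corridor_halfwidth = 82.5,
                                   after_frames = 1) {
  empty <- tibble::tibble(frame = integer(), t_h = double(), x_um = double(),
                          y_um = double(), separation_um = double(),
                          reversal_deg = double())
  ann <- events[events$type == "annihilation", , drop = FALSE]
  if (nrow(ann) == 0) return(empty)
  rows <- lapply(seq_len(nrow(ann)), function(k) {
    ev <- ann[k, ]
    others <- tracks[tracks$frame == ev$frame &
                       !(tracks$track_id %in% c(ev$plus_track, ev$minus_track)), ]
    if (nrow(others) > 0) {
      d <- sqrt((others$x_um - ev$x_um)^2 + (others$y_um - ev$y_um)^2)
      if (any(d < isolation_radius)) return(NULL)
    }
    # simultaneous pair deaths spoil each other's corridor as well
    twin <- ann[-k, , drop = FALSE]
    if (nrow(twin) > 0) {
      d <- sqrt((twin$x_um - ev$x_um)^2 + (twin$y_um - ev$y_um)^2)
      if (any(abs(twin$frame - ev$frame) <= 1 & d < isolation_radius)) return(NULL)
    }
    if (dipole_check) {
      fb <- fields[fields$frame == ev$frame, , drop = FALSE]
      dd <- sqrt((fb$x_um - ev$x_um)^2 + (fb$y_um - ev$y_um)^2)
      amb <- fb[dd > ambient_annulus[1] & dd < ambient_annulus[2], ]
      if (nrow(amb) == 0) return(NULL)
      th <- atan2(amb$v_umph, amb$u_umph)
      ambient <- atan2(mean(sin(th)), mean(cos(th)))
      pe <- tracks[tracks$track_id == ev$plus_track, ]
      me <- tracks[tracks$track_id == ev$minus_track, ]
      cb <- corridor_direction(fb,
        c(tail(pe$x_um, 1), tail(pe$y_um, 1)),
        c(tail(me$x_um, 1), tail(me$y_um, 1)), corridor_halfwidth)
      if (is.na(cb)) return(NULL)
      mis <- abs((cb - ambient + pi) %% (2 * pi) - pi)
      if (mis < pi / 2) return(NULL)
    }
    a <- tryCatch(reversal_angle(ev, tracks, fields,
                                 corridor_halfwidth = corridor_halfwidth,
                                 after_frames = after_frames),
                  error = function(e) NA_real_)
    if (!is.finite(a)) return(NULL)
    tibble::tibble(frame = ev$frame, t_h = ev$t_h, x_um = ev$x_um,
                   y_um = ev$y_um, separation_um = ev$separation_um,
                   reversal_deg = a)
  })
  out <- dplyr::bind_rows(rows)
  if (nrow(out) == 0) empty else out
}

#' Circular mean of angles in degrees
#'
#' @param deg Angles in degrees.
#' @return Circular mean in degrees, in `[-180, 180]`.
#' @export
circular_mean_deg <- function(deg) {
  rad <- deg * pi / 180
  atan2(mean(sin(rad)), mean(cos(rad))) * 180 / pi
}
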