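#' Relative motility against an anchor cell
#'
#' Registers every frame by subtracting the anchor cell's displacement, so
#' the anchor becomes a stationary reference point, then reports for each
#' other cell the sum of per-frame Euclidean step lengths divided by the
#' window duration in hours. In a rigidly co-moving patch every cell scores
#' zero; neighbor rearrangements raise the score.
#'
#' @param trajectories A tibble `track_id`, `frame`, `x_um`, `y_um`.
#' @param anchor_id Track id of the anchor cell; it must be present in every
#'   frame of the window and is excluded from the output.
#' @param window_frames Number of frames analyzed, starting at the first
#'   frame the anchor appears in (default 101, i.e. 6.7 h at 4-min frames).
#' @param frame_interval_h Frame interval in hours; defaults to the
#'   `frame_interval_h` attribute of `trajectories`.
#' @return A tibble `track_id`, `n_steps`, `path_um`,
#'   `relative_motility_umph`.
#' @export
relative_motility <- function(trajectories, anchor_id, window_frames = 101,
                              frame_interval_h = NULL) {
  frame_interval_h <- frame_interval_h %||% attr(trajectories, "frame_interval_h")
  if (is.null(frame_interval_h)) {
    abort("supply `frame_interval_h` (not stored on `trajectories`)")
  }
  anchor <- trajectories[trajectories$track_id == anchor_id, , drop = FALSE]
  if (nrow(anchor) == 0) abort("anchor track not found")
  anchor <- anchor[order(anchor$frame), ]
  f0 <- min(anchor$frame)
  window <- f0:(f0 + window_frames - 1)
  missing <- setdiff(window, anchor$frame)
  if (length(missing)) {
    abort(sprintf("anchor track has gaps in the window (missing frames: %s)",
                  paste(head(missing, 5), collapse = ", ")))
  }
  anchor <- anchor[anchor$frame %in% window, ]
  shift <- tibble::tibble(frame = anchor$frame,
                          ax = anchor$x_um - anchor$x_um[1],
                          ay = anchor$y_um - anchor$y_um[1])
  sub <- trajectories[trajectories$frame %in% window &
                        trajectories$track_id != anchor_id, , drop = FALSE]
  sub <- dplyr::left_join(sub, shift, by = "frame")
  sub <- dplyr::mutate(sub, rx = .data$x_um - .data$ax, ry = .data$y_um - .data$ay)
  hours <- (window_frames - 1) * frame_interval_h
  dplyr::summarise(
    dplyr::group_by(dplyr::arrange(sub, .data$track_id, .data$frame),
                    .data$track_id),
    n_steps = dplyr::n() - 1L,
    path_um = sum(sqrt(diff(.data$rx)^2 + diff(.data$ry)^2)),
    relative_motility_umph = .data$path_um / hours,
    .groups = "drop")
}

#' Pairwise squared-distance diffusion analysis
#'
#' Identifies pairs of tracks whose initial separation is below
#' `initial_radius`, follows the squared inter-pair distance per frame, and
#' fits an ordinary least-squares line to the mean squared distance versus
#' time. The slope (um^2/h) reads out the solid (near zero) versus liquid
#' (positive) character of the relative cell motion; no categorical call is
#' made.
#'
#' @param trajectories A tibble `track_id`, `frame`, `x_um`, `y_um`.
#' @param initial_radius Pair-selection radius in the first analyzed frame,
#'   um (default 23).
#' @param frame_interval_h Frame interval in hours; defaults to the
#'   attribute on `trajectories`.
#' @param window Optional `c(first, last)` frame range; default all frames.
#'   Only pairs with both tracks complete over the window are used.
#' @param min_pairs Warn when fewer than this many qualifying pairs are
#'   found (default 30).
#' @return An object of class `pair_diffusion`; see
#'   [tidy.pair_diffusion()] and [glance.pair_diffusion()].
#' @export
pair_msd <- function(trajectories, initial_radius = 23,
                     frame_interval_h = NULL, window = NULL, min_pairs = 30) {
  frame_interval_h <- frame_interval_h %||% attr(trajectories, "frame_interval_h")
  if (is.null(frame_interval_h)) {
    abort("supply `frame_interval_h` (not stored on `trajectories`)")
  }
  frames <- sort(unique(trajectories$frame))
  if (!is.null(window)) frames <- frames[frames >= window[1] & frames <= window[2]]
  if (length(frames) < 2) abort("analysis window must span at least 2 frames")
  sub <- trajectories[trajectories$frame %in% frames, , drop = FALSE]
  complete <- dplyr::summarise(dplyr::group_by(sub, .data$track_id),
                               n = dplyr::n(), .groups = "drop")
  keep <- complete$track_id[complete$n == length(frames)]
  sub <- sub[sub$track_id %in% keep, , drop = FALSE]
  first <- sub[sub$frame == frames[1], , drop = FALSE]
  if (nrow(first) < 2) abort("no qualifying pairs (need >= 2 complete tracks)")
  dm <- as.matrix(stats::dist(cbind(first$x_um, first$y_um)))
  pairs <- which(upper.tri(dm) & dm < initial_radius, arr.ind = TRUE)
  if (nrow(pairs) == 0) abort("no qualifying pairs within `initial_radius`")
  if (nrow(pairs) < min_pairs) {
    warn(sprintf("only %d qualifying pairs (requested at least %d)",
                 nrow(pairs), min_pairs))
  }
  ids_a <- first$track_id[pairs[, 1]]
  ids_b <- first$track_id[pairs[, 2]]
  wide_x <- msd_wide(sub, frames, "x_um")
  wide_y <- msd_wide(sub, frames, "y_um")
  sq <- (wide_x[, as.character(ids_a), drop = FALSE] -
           wide_x[, as.character(ids_b), drop = FALSE])^2 +
    (wide_y[, as.character(ids_a), drop = FALSE] -
       wide_y[, as.character(ids_b), drop = FALSE])^2
  msd <- rowMeans(sq)
  t_h <- (frames - frames[1]) * frame_interval_h
  fit <- lm(msd ~ t_h)
  structure(
    list(lag_h = t_h, msd_um2 = unname(msd), n_pairs = nrow(pairs),
         slope_um2ph = unname(coef(fit)[2]), intercept_um2 = unname(coef(fit)[1]),
         fit = fit),
    class = "pair_diffusion"
  )
}

msd_wide <- function(sub, frames, col) {
  m <- tapply(sub[[col]], list(sub$frame, sub$track_id), mean)
  m[as.character(frames), , drop = FALSE]
}

#' @rdname pair_msd
#' @param x A `pair_diffusion` object.
#' @param ... Unused.
#' @method tidy pair_diffusion
#' @export
tidy.pair_diffusion <- function(x, ...) {
  tibble::tibble(lag_h = x$lag_h, msd_um2 = x$msd_um2)
}

#' @rdname pair_msd
#' @method glance pair_diffusion
#' @export
glance.pair_diffusion <- function(x, ...) {
  tibble::tibble(slope_um2ph = x$slope_um2ph, intercept_um2 = x$intercept_um2,
                 n_pairs = x$n_pairs)
}

#' @export
print.pair_diffusion <- function(x, ...) {
  cat(sprintf("<pair_diffusion> %d pairs, slope %.4g um^2/h\n",
              x$n_pairs, x$slope_um2ph))
  invisible(x)
}
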