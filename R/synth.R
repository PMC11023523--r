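#' Specify a point defect for field synthesis
#'
#' @param x,y Defect center in micrometers.
#' @param charge Topological charge, +1 (vortex/aster family) or -1 (saddle).
#' @param psi Spin phase in radians. For `charge = +1`, `psi = pi/2` gives a
#'   counterclockwise vortex and `-pi/2` a clockwise one (`0` gives an
#'   outward aster); for `charge = -1` it sets the saddle orientation.
#' @return A one-row tibble.
#' @export
defect_spec <- function(x, y, charge, psi = pi / 2) {
  stopifnot(charge %in% c(-1, 1))
  tibble::tibble(x_um = as.double(x), y_um = as.double(y),
                 charge = as.integer(charge), psi = as.double(psi))
}

#' Compose a velocity field from point defects
#'
#' Standard angle superposition for point defects in a polar field: the
#' direction field is `theta(x, y) = sum_k q_k atan2(y - y_k, x - x_k) + psi`
#' and the velocity is `speed * (cos theta, sin theta)`. The winding number
#' around each center equals its charge; `psi` is the sum of the individual
#' spin phases.
#'
#' @param defects A tibble of [defect_spec()] rows (may be empty: uniform
#'   field of direction `psi`).
#' @param grid A [field_grid()].
#' @param speed Uniform flow speed in um/h (default 35).
#' @param frame,t_h Frame index and time stamp for the output.
#' @return A velocity-field tibble (see [velocity_field()]).
#' @export
compose_defect_field <- function(defects, grid, speed = 35,
                                 frame = 1L, t_h = 0) {
  stopifnot(inherits(grid, "field_grid"))
  xy <- expand.grid(x = grid$xs, y = grid$ys)
  theta <- rep(0, nrow(xy))
  if (nrow(defects) > 0) {
    if (nrow(defects) > 1) {
      dmin <- min(stats::dist(cbind(defects$x_um, defects$y_um)))
      if (dmin <= 0) abort("coincident defect centers")
      if (dmin < 2 * grid$spacing) {
        warn("defect centers closer than 2 grid spacings; cores overlap")
      }
    }
    for (k in seq_len(nrow(defects))) {
      theta <- theta + defects$charge[k] *
        atan2(xy$y - defects$y_um[k], xy$x - defects$x_um[k])
    }
    theta <- theta + sum(defects$psi)
  }
  velocity_field(xy$x, xy$y, speed * cos(theta), speed * sin(theta),
                 frame = frame, t_h = t_h)
}

#' Velocity field with exponentially correlated direction noise
#'
#' Generates zero-mean Gaussian perturbations of the flow direction with
#' isotropic spatial autocorrelation approximately `exp(-r / lambda)`, by
#' Fourier filtering white noise with the square root of the 2D spectral
#' density of the exponential kernel, `S(k) = 2 pi lambda^2
#' (1 + (k lambda)^2)^(-3/2)`. The field is `speed * (cos theta, sin theta)`
#' with `theta = mean_direction + sigma * g(x, y)`.
#'
#' @param lambda_corr Target correlation length of the direction field, um
#'   (must exceed the grid spacing).
#' @param grid A [field_grid()].
#' @param speed Flow speed in um/h.
#' @param mean_direction Mean flow direction, radians.
#' @param sigma Standard deviation of the direction perturbation, radians
#'   (default 0.2, about 11 degrees RMS -- the small-angle regime in which
#'   the direction field's exponential autocorrelation transfers linearly to
#'   the velocity correlation; larger values add a cosine-weighting baseline
#'   of order sigma^2 at long range).
#' @param seed Optional RNG seed for reproducibility.
#' @param frame,t_h Frame index and time stamp.
#' @return A velocity-field tibble.
#' @export
correlated_noise_field <- function(lambda_corr, grid, speed = 35,
                                   mean_direction = 0, sigma = 0.2,
                                   seed = NULL, frame = 1L, t_h = 0) {
  stopifnot(inherits(grid, "field_grid"), lambda_corr > grid$spacing)
  g <- with_seed_(seed, gaussian_field_exp(grid$nx, grid$ny,
                                           lambda_corr / grid$spacing))
  theta <- mean_direction + sigma * g
  xy <- expand.grid(x = grid$xs, y = grid$ys)
  velocity_field(xy$x, xy$y, speed * cos(as.vector(theta)),
                 speed * sin(as.vector(theta)), frame = frame, t_h = t_h)
}

# unit-variance Gaussian field on an nx x ny grid with correlation
# ~ exp(-r / lam) (lam in grid units), via spectral filtering on an
# enlarged periodic domain to suppress wrap-around correlation
gaussian_field_exp <- function(nx, ny, lam) {
  mx <- 2^ceiling(log2(2 * max(nx, 4 * lam)))
  my <- 2^ceiling(log2(2 * max(ny, 4 * lam)))
  kx <- 2 * pi * c(0:(mx / 2), -(mx / 2 - 1):-1) / mx
  ky <- 2 * pi * c(0:(my / 2), -(my / 2 - 1):-1) / my
  k2 <- outer(kx^2, ky^2, `+`)
  s <- (1 + k2 * lam^2)^(-1.5)
  w <- matrix(rnorm(mx * my), mx, my)
  f <- Re(fft(fft(w) * sqrt(s), inverse = TRUE)) / (mx * my)
  f <- f[seq_len(nx), seq_len(ny), drop = FALSE]
  (f - mean(f)) / sd(as.vector(f))
}

#' Grid particle velocities onto a PIV-like lattice
#'
#' Emulates the sampling of particle image velocimetry: each grid node
#' reports the mean velocity of the particles inside a square interrogation
#' window centered on it. The defaults (66 um node spacing, 165 um window)
#' reproduce a 165-um window with 99-um overlap between consecutive windows.
#' Empty windows are masked (their nodes are absent from the output).
#'
#' @param particles Data frame with columns `x_um`, `y_um`, `vx_umph`,
#'   `vy_umph` (one frame of particles).
#' @param spacing Grid node spacing, um.
#' @param window Side of the square interrogation window, um.
#' @param grid Optional [field_grid()]; by default a grid covering the
#'   particle bounding box.
#' @param frame,t_h Frame index and time stamp for the output.
#' @return A velocity-field tibble.
#' @export
grid_particle_velocities <- function(particles, spacing = 66, window = 165,
                                     grid = NULL, frame = 1L, t_h = 0) {
  stopifnot(all(c("x_um", "y_um", "vx_umph", "vy_umph") %in% names(particles)))
  if (nrow(particles) == 0) abort("no particles to grid")
  if (is.null(grid)) {
    x0 <- min(particles$x_um); y0 <- min(particles$y_um)
    nx <- max(3, floor((max(particles$x_um) - x0) / spacing) + 1)
    ny <- max(3, floor((max(particles$y_um) - y0) / spacing) + 1)
    grid <- field_grid(nx, ny, spacing, origin = c(x0, y0))
  }
  half <- window / 2
  # each particle feeds every node whose window contains it
  ix_lo <- ceiling((particles$x_um - grid$origin[1] - half) / grid$spacing) + 1
  ix_hi <- floor((particles$x_um - grid$origin[1] + half) / grid$spacing) + 1
  iy_lo <- ceiling((particles$y_um - grid$origin[2] - half) / grid$spacing) + 1
  iy_hi <- floor((particles$y_um - grid$origin[2] + half) / grid$spacing) + 1
  span_x <- ix_hi - ix_lo + 1
  reps <- pmax(span_x, 0)
  pid <- rep(seq_len(nrow(particles)), reps)
  ix <- unlist(lapply(which(reps > 0), function(p) ix_lo[p]:ix_hi[p]))
  span_y <- iy_hi - iy_lo + 1
  reps2 <- pmax(span_y[pid], 0)
  pid2 <- rep(pid, reps2)
  ix2 <- rep(ix, reps2)
  iy2 <- unlist(lapply(which(reps2 > 0), function(q) iy_lo[pid[q]]:iy_hi[pid[q]]))
  ok <- ix2 >= 1 & ix2 <= grid$nx & iy2 >= 1 & iy2 <= grid$ny
  if (!any(ok)) abort("no particle falls inside any interrogation window")
  node <- (iy2[ok] - 1) * grid$nx + ix2[ok]
  su <- rowsum(particles$vx_umph[pid2[ok]], node)
  sv <- rowsum(particles$vy_umph[pid2[ok]], node)
  cnt <- rowsum(rep(1, sum(ok)), node)
  nodes <- as.integer(rownames(su))
  gx <- grid$xs[(nodes - 1) %% grid$nx + 1]
  gy <- grid$ys[(nodes - 1) %/% grid$nx + 1]
  velocity_field(gx, gy, su / cnt, sv / cnt, frame = frame, t_h = t_h)
}

#' Synthetic trajectory tables with known relative-motion regime
#'
#' Ground-truth fixtures for the kinematics module: `rigid` tracks share one
#' displacement series (no relative motion), `diffusive` tracks are
#' independent 2D Gaussian random walks, and `mixed` adds a shared drift to
#' independent walks.
#'
#' @param regime `"rigid"`, `"diffusive"` or `"mixed"`.
#' @param n_cells Number of tracks.
#' @param n_frames Number of frames (>= 2); default 101.
#' @param frame_interval_h Frame interval in hours (default 4 min, so that
#'   101 frames span 6.7 h).
#' @param step_sd Per-frame random-walk step standard deviation per
#'   coordinate, um (diffusive/mixed).
#' @param drift_sd Per-frame shared-drift step SD, um (rigid/mixed).
#' @param spread Initial positions are uniform in a `spread x spread` um box.
#' @param seed Optional RNG seed.
#' @return A tibble with columns `track_id`, `frame`, `x_um`, `y_um` and
#'   attribute `frame_interval_h`; ground-truth parameters in attribute
#'   `truth`.
#' @export
synth_trajectories <- function(regime = c("rigid", "diffusive", "mixed"),
                               n_cells = 30, n_frames = 101,
                               frame_interval_h = 1 / 15, step_sd = 1,
                               drift_sd = 2, spread = 150, seed = NULL) {
  regime <- match.arg(regime)
  stopifnot(n_frames >= 2, n_cells >= 1)
  with_seed_(seed, {
    x0 <- runif(n_cells, 0, spread)
    y0 <- runif(n_cells, 0, spread)
    drift <- if (regime %in% c("rigid", "mixed")) {
      cbind(cumsum(c(0, rnorm(n_frames - 1, sd = drift_sd))),
            cumsum(c(0, rnorm(n_frames - 1, sd = drift_sd))))
    } else matrix(0, n_frames, 2)
    walk_sd <- if (regime == "rigid") 0 else step_sd
    out <- lapply(seq_len(n_cells), function(i) {
      wx <- cumsum(c(0, rnorm(n_frames - 1, sd = walk_sd)))
      wy <- cumsum(c(0, rnorm(n_frames - 1, sd = walk_sd)))
      tibble::tibble(track_id = i, frame = seq_len(n_frames),
                     x_um = x0[i] + drift[, 1] + wx,
                     y_um = y0[i] + drift[, 2] + wy)
    })
    tbl <- dplyr::bind_rows(out)
    attr(tbl, "frame_interval_h") <- frame_interval_h
    attr(tbl, "truth") <- list(regime = regime, step_sd = walk_sd,
                               drift_sd = drift_sd)
    tbl
  })
}
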