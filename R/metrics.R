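#' Mean migration speed
#'
#' Mean of the per-sample velocity magnitudes, in um/h. Accepts either a
#' velocity-field frame (`u_umph`, `v_umph`) or a particle snapshot
#' (`vx_umph`, `vy_umph`).
#'
#' @param x A data frame with velocity components.
#' @return Scalar mean speed (um/h).
#' @export
mean_speed <- function(x) {
  if (all(c("u_umph", "v_umph") %in% names(x))) {
    u <- x$u_umph; v <- x$v_umph
  } else if (all(c("vx_umph", "vy_umph") %in% names(x))) {
    u <- x$vx_umph; v <- x$vy_umph
  } else {
    abort("need velocity columns `u_umph`/`v_umph` or `vx_umph`/`vy_umph`")
  }
  ok <- is.finite(u) & is.finite(v)
  if (!any(ok)) abort("no valid velocity samples")
  mean(sqrt(u[ok]^2 + v[ok]^2))
}

#' Spatial velocity correlation function
#'
#' For each integer lag r along the x grid axis,
#' `C(r) = 1 / (Nx Ny (Nx - r)) * sum over (x, y) with x + r < Nx of
#' [du(x,y) du(x+r,y) + dv(x,y) dv(x+r,y)] * cos(theta(x,y) - theta(x+r,y))`,
#' where `du`, `dv` are the velocity fluctuations about the frame's spatial
#' mean velocity and `theta` is the velocity direction. Lags are reported in
#' um via the grid spacing.
#'
#' A spatially constant frame has zero fluctuations everywhere; its
#' normalized correlation is defined as 1 at all lags (a perfectly ordered
#' field is maximally correlated) and the correlation length is
#' right-censored.
#'
#' @param field A velocity-field tibble (one frame).
#' @return An object of class `velocity_correlation` with elements
#'   `r_um`, `c_raw`, `c_norm`, `spacing`, `constant_field`.
#' @export
correlation_function <- function(field) {
  fm <- field_matrices(field)
  nx <- fm$grid$nx; ny <- fm$grid$ny
  if (nx < 2) abort("need at least 2 grid columns")
  u <- fm$u; v <- fm$v
  if (!any(fm$valid)) abort("all nodes masked")
  mu <- mean(u[fm$valid]); mv <- mean(v[fm$valid])
  du <- u - mu; dv <- v - mv
  theta <- atan2(v, u)
  lags <- 0:(nx - 2)
  c_raw <- vapply(lags, function(r) {
    i1 <- seq_len(nx - r); i2 <- i1 + r
    ok <- fm$valid[i1, , drop = FALSE] & fm$valid[i2, , drop = FALSE]
    if (!any(ok)) return(NA_real_)
    term <- (du[i1, , drop = FALSE] * du[i2, , drop = FALSE] +
             dv[i1, , drop = FALSE] * dv[i2, , drop = FALSE]) *
      cos(theta[i1, , drop = FALSE] - theta[i2, , drop = FALSE])
    sum(term[ok]) / (nx * ny * (nx - r))
  }, double(1))
  constant <- is.finite(c_raw[1]) && c_raw[1] <= 1e-12 * max(mu^2 + mv^2, 1)
  c_norm <- if (constant) rep(1, length(lags)) else c_raw / c_raw[1]
  structure(
    list(r_um = lags * fm$grid$spacing, c_raw = c_raw, c_norm = c_norm,
         spacing = fm$grid$spacing, constant_field = constant),
    class = "velocity_correlation"
  )
}

#' Correlation length from a fitted exponential decay
#'
#' Fits `a * exp(-r / b)` to the normalized correlation (unweighted least
#' squares over lags r >= 1) and reports the distance `xi` at which the
#' fitted curve crosses 0.5. If the fitted curve never reaches 0.5 within
#' the observed lag range, `xi` is right-censored at the maximum lag and
#' flagged.
#'
#' @param corr A `velocity_correlation` from [correlation_function()].
#' @return The input object augmented with `amplitude`, `decay_um`, `xi_um`,
#'   `censored`.
#' @export
correlation_length <- function(corr) {
  stopifnot(inherits(corr, "velocity_correlation"))
  r <- corr$r_um; cn <- corr$c_norm
  max_r <- max(r)
  if (corr$constant_field) {
    corr$amplitude <- 1; corr$decay_um <- Inf
    corr$xi_um <- max_r; corr$censored <- TRUE
    return(corr)
  }
  sel <- r >= corr$spacing & is.finite(cn)
  fit <- fit_exponential(r[sel], cn[sel])
  a <- fit[["a"]]; b <- fit[["b"]]
  xi <- b * log(2 * a)                       # a exp(-xi/b) = 0.5
  if (!is.finite(xi) || xi < 0 || xi > max_r) {
    xi <- max_r
    censored <- TRUE
  } else {
    censored <- FALSE
  }
  corr$amplitude <- a; corr$decay_um <- b
  corr$xi_um <- xi; corr$censored <- censored
  corr
}

# least squares for a * exp(-r / b): profile the amplitude analytically on a
# log-spaced grid of decay scales, then polish with Nelder-Mead; robust on
# noisy or non-monotone correlation curves where Gauss-Newton stalls
fit_exponential <- function(r, y) {
  profile <- function(b) {
    e <- exp(-r / b)
    a <- sum(y * e) / sum(e^2)
    c(a = a, sse = sum((y - a * e)^2))
  }
  bs <- exp(seq(log(min(r[r > 0]) / 4), log(8 * max(r)), length.out = 80))
  prof <- vapply(bs, profile, double(2))
  k <- which.min(prof["sse", ])
  start <- c(a = prof["a", k], logb = log(bs[k]))
  lo <- log(min(r[r > 0]) / 4); hi <- log(8 * max(r))
  opt <- stats::optim(start, function(p) {
    if (p[2] < lo || p[2] > hi) return(1e12)
    sum((y - p[1] * exp(-r / exp(p[2])))^2)
  }, method = "Nelder-Mead")
  b <- exp(min(max(unname(opt$par[2]), lo), hi))
  e <- exp(-r / b)
  c(a = sum(y * e) / sum(e^2), b = b)
}

#' @export
print.velocity_correlation <- function(x, ...) {
  cat(sprintf("<velocity_correlation> %d lags, spacing %.3g um", length(x$r_um),
              x$spacing))
  if (!is.null(x$xi_um)) {
    cat(sprintf(", xi = %.4g um%s", x$xi_um, if (x$censored) " (censored)" else ""))
  }
  cat("\n")
  invisible(x)
}

#' @rdname correlation_function
#' @param x A `velocity_correlation` object.
#' @param ... Unused.
#' @method tidy velocity_correlation
#' @export
tidy.velocity_correlation <- function(x, ...) {
  out <- tibble::tibble(r_um = x$r_um, c_raw = x$c_raw, c_norm = x$c_norm)
  if (!is.null(x$amplitude)) {
    out$c_fit <- x$amplitude * exp(-x$r_um / x$decay_um)
  }
  out
}

#' @rdname correlation_length
#' @param x A `velocity_correlation` object.
#' @param ... Unused.
#' @method glance velocity_correlation
#' @export
glance.velocity_correlation <- function(x, ...) {
  tibble::tibble(xi_um = x$xi_um %||% NA_real_,
                 amplitude = x$amplitude %||% NA_real_,
                 decay_um = x$decay_um %||% NA_real_,
                 censored = x$censored %||% NA,
                 constant_field = x$constant_field)
}

#' Vorticity field
#'
#' `omega = dv/dx - du/dy`, central differences in the interior and
#' one-sided differences at the edges. Positive vorticity is
#' counterclockwise.
#'
#' @param field A velocity-field tibble (one frame) on a grid of at
#'   least 3 x 3.
#' @return A tibble `x_um`, `y_um`, `omega_per_h` at nodes where the
#'   derivative stencils are valid.
#' @export
vorticity_field <- function(field) {
  fm <- field_matrices(field)
  if (fm$grid$nx < 3 || fm$grid$ny < 3) abort("grid must be at least 3 x 3")
  h <- fm$grid$spacing
  dvdx <- difference_x(fm$v, h)
  dudy <- difference_y(fm$u, h)
  omega <- dvdx - dudy
  idx <- which(is.finite(omega), arr.ind = TRUE)
  tibble::tibble(x_um = fm$grid$xs[idx[, 1]], y_um = fm$grid$ys[idx[, 2]],
                 omega_per_h = omega[idx])
}

difference_x <- function(m, h) {
  nx <- nrow(m)
  d <- matrix(NA_real_, nx, ncol(m))
  d[2:(nx - 1), ] <- (m[3:nx, ] - m[1:(nx - 2), ]) / (2 * h)
  d[1, ] <- (m[2, ] - m[1, ]) / h
  d[nx, ] <- (m[nx, ] - m[nx - 1, ]) / h
  d
}

difference_y <- function(m, h) {
  ny <- ncol(m)
  d <- matrix(NA_real_, nrow(m), ny)
  d[, 2:(ny - 1)] <- (m[, 3:ny] - m[, 1:(ny - 2)]) / (2 * h)
  d[, 1] <- (m[, 2] - m[, 1]) / h
  d[, ny] <- (m[, ny] - m[, ny - 1]) / h
  d
}

#' Mean migration direction in a region over time
#'
#' Circular mean of the velocity directions among grid nodes inside a
#' rectangular region, per frame. Frames whose resultant vector is
#' (numerically) zero are flagged `undefined` and get `NA` direction.
#'
#' @param fields A multi-frame velocity-field tibble.
#' @param xlim,ylim Region bounds in um.
#' @return A tibble `frame`, `t_h`, `theta_rad`, `resultant`, `undefined`.
#' @export
region_direction <- function(fields, xlim, ylim) {
  sel <- fields$x_um >= xlim[1] & fields$x_um <= xlim[2] &
    fields$y_um >= ylim[1] & fields$y_um <= ylim[2]
  if (!any(sel)) abort("region contains no grid nodes")
  sub <- fields[sel, , drop = FALSE]
  dplyr::summarise(
    dplyr::group_by(sub, .data$frame),
    t_h = .data$t_h[1],
    theta_rad = {
      th <- atan2(.data$v_umph, .data$u_umph)
      s <- mean(sin(th)); c <- mean(cos(th))
      if (sqrt(s^2 + c^2) < 1e-9) NA_real_ else atan2(s, c)
    },
    resultant = {
      th <- atan2(.data$v_umph, .data$u_umph)
      sqrt(mean(sin(th))^2 + mean(cos(th))^2)
    },
    .groups = "drop"
  ) |>
    dplyr::mutate(undefined = !is.finite(.data$theta_rad))
}
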