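test_that("mean speed is the mean velocity magnitude", {
  g <- field_grid(5, 5, 66)
  xy <- expand.grid(x = g$xs, y = g$ys)
  f35 <- velocity_field(xy$x, xy$y, rep(35, 25), rep(0, 25))
  expect_equal(mean_speed(f35), 35)
  f345 <- velocity_field(xy$x, xy$y, rep(3, 25), rep(4, 25))
  expect_equal(mean_speed(f345), 5)
  withr::with_seed(1, {
    u <- rnorm(25, sd = 10); v <- rnorm(25, sd = 10)
  })
  fm <- velocity_field(xy$x, xy$y, u, v)
  expect_equal(mean_speed(fm), mean(sqrt(u^2 + v^2)))
  snap <- tibble::tibble(vx_umph = u, vy_umph = v)
  expect_equal(mean_speed(snap), mean(sqrt(u^2 + v^2)))
})

test_that("the correlation function matches its printed form on fixtures", {
  g <- field_grid(48, 48, 33)
  # spatially constant field: zero fluctuations, unit normalized correlation
  xy <- expand.grid(x = g$xs, y = g$ys)
  const <- velocity_field(xy$x, xy$y, rep(20, nrow(xy)), rep(15, nrow(xy)))
  cc <- correlation_function(const)
  expect_true(all(abs(cc$c_raw) < 1e-9))
  expect_true(all(cc$c_norm == 1))
  xi_const <- correlation_length(cc)
  expect_true(xi_const$censored)
  # direction noise at the grid scale decorrelates within a few lags
  wn <- correlated_noise_field(34, g, seed = 2)
  cw <- correlation_function(wn)
  expect_lt(mean(abs(cw$c_norm[4:10])), 0.12)
  # exponential fixture decays at the planted scale (seed-averaged curve)
  ge <- field_grid(64, 64, 50)
  ce <- rowMeans(sapply(1:4, function(s)
    correlation_function(correlated_noise_field(300, ge, seed = s))$c_norm))
  lag_um <- (seq_along(ce) - 1) * 50
  sel <- lag_um > 0 & lag_um < 600
  expect_lt(mean(abs(ce[sel] - exp(-lag_um[sel] / 300))), 0.05)
})

test_that("xi is the 0.5 crossing of the fitted exponential", {
  # exact closed form: a perfect exp(-r/lambda) curve gives xi = lambda ln 2
  r <- seq(0, 1500, by = 33)
  corr <- structure(list(r_um = r, c_raw = exp(-r / 300),
                         c_norm = exp(-r / 300), spacing = 33,
                         constant_field = FALSE),
                    class = "velocity_correlation")
  out <- correlation_length(corr)
  expect_equal(out$xi_um, 300 * log(2), tolerance = 1e-6)
  expect_false(out$censored)
  # the fitted curve evaluated at xi equals the 0.5 threshold exactly
  expect_equal(out$amplitude * exp(-out$xi_um / out$decay_um), 0.5,
               tolerance = 1e-9)
  # glance/tidy expose the fit
  gl <- glance(out)
  expect_equal(gl$xi_um, out$xi_um)
  td <- tidy(out)
  expect_named(td, c("r_um", "c_raw", "c_norm", "c_fit"))
})

test_that("the xi estimator recovers planted correlation lengths", {
  # scale-invariant fixtures: each lambda is sampled at lambda/6 spacing so
  # every case resolves its structure equally (64 x 64 nodes, ~10.7 lambda
  # across); the median over seeds guards against the right-skew of
  # exponential fits on single noisy frames
  for (lambda in c(150, 300, 600)) {
    g <- field_grid(64, 64, lambda / 6)
    xis <- sapply(1:8, function(s) {
      f <- correlated_noise_field(lambda, g, seed = 100 + s)
      correlation_length(correlation_function(f))$xi_um
    })
    expect_lt(abs(median(xis) - lambda * log(2)) / (lambda * log(2)), 0.15)
  }
})

test_that("vorticity matches analytic flows", {
  g <- field_grid(15, 15, 66)
  xy <- expand.grid(x = g$xs, y = g$ys)
  omega0 <- 0.2
  cx <- mean(g$xs); cy <- mean(g$ys)
  rigid <- velocity_field(xy$x, xy$y, -omega0 * (xy$y - cy), omega0 * (xy$x - cx))
  vr <- vorticity_field(rigid)
  expect_true(all(abs(vr$omega_per_h - 2 * omega0) < 1e-9))
  uniform <- velocity_field(xy$x, xy$y, rep(12, nrow(xy)), rep(-5, nrow(xy)))
  expect_true(all(abs(vorticity_field(uniform)$omega_per_h) < 1e-12))
  shear <- velocity_field(xy$x, xy$y, xy$y, rep(0, nrow(xy)))
  expect_true(all(abs(vorticity_field(shear)$omega_per_h + 1) < 1e-9))
  # curl-free (gradient) flow: u = x, v = y
  gradf <- velocity_field(xy$x, xy$y, xy$x, xy$y)
  expect_true(all(abs(vorticity_field(gradf)$omega_per_h) < 1e-9))
})

test_that("metrics are isotropic under field rotation", {
  g <- field_grid(48, 48, 42)
  rotate90 <- function(f) {
    tibble::tibble(frame = f$frame, t_h = f$t_h,
                   x_um = -f$y_um + max(f$y_um), y_um = f$x_um,
                   u_umph = -f$v_umph, v_umph = f$u_umph)
  }
  f1 <- correlated_noise_field(250, g, seed = 7, mean_direction = 0.3)
  expect_equal(mean_speed(f1), 35, tolerance = 1e-9)
  expect_equal(mean_speed(rotate90(f1)), mean_speed(f1))
  # the x-lag sampling is isotropic in expectation: seed-averaged curves of
  # original and rotated fields agree
  cs <- sapply(1:12, function(s) {
    f <- correlated_noise_field(250, g, seed = 6 + s, mean_direction = 0.3)
    cbind(correlation_function(f)$c_norm, correlation_function(rotate90(f))$c_norm)
  })
  n <- nrow(cs) / 2
  c1 <- rowMeans(cs[1:n, , drop = FALSE])
  c2 <- rowMeans(cs[(n + 1):(2 * n), , drop = FALSE])
  expect_lt(mean(abs(c1 - c2)), 0.05)
})

test_that("region direction is the circular mean and flags zero resultants", {
  g <- field_grid(6, 6, 66)
  xy <- expand.grid(x = g$xs, y = g$ys)
  plusx <- velocity_field(xy$x, xy$y, rep(35, nrow(xy)), rep(0, nrow(xy)))
  rd <- region_direction(plusx, xlim = c(0, 400), ylim = c(0, 400))
  expect_equal(rd$theta_rad, 0)
  minusx <- velocity_field(xy$x, xy$y, rep(-35, nrow(xy)), rep(0, nrow(xy)))
  rd2 <- region_direction(minusx, xlim = c(0, 400), ylim = c(0, 400))
  expect_equal(abs(rd2$theta_rad), pi)
  balanced <- velocity_field(xy$x, xy$y, rep(0, nrow(xy)),
                             rep(c(35, -35), length.out = nrow(xy)))
  rd3 <- region_direction(balanced, xlim = c(0, 400), ylim = c(0, 400))
  expect_true(rd3$undefined)
  expect_error(region_direction(plusx, c(1e5, 2e5), c(1e5, 2e5)), "no grid nodes")
})
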