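test_that("pair force matches the hand-derived spring law", {
  net <- two_particle_network(r = 12, d_ij = 10)
  p <- sim_params(v_c = 35, k_tilde = 10 / 35, b_tilde = 0, d = 1, zeta = 1)
  expect_equal(p$k, 10)                      # K = k_tilde zeta V_c / d
  p$k <- 1; p$b <- 0                         # K = 1, B = 0 for the oracle case
  f <- elastic_forces(net$points, net, p)
  # stretched by 2 -> magnitude K * 2, attractive
  expect_equal(f$fx[1], 2, tolerance = 1e-12)
  expect_equal(f$fx[2], -2, tolerance = 1e-12)
  expect_equal(f$fy, c(0, 0))
  # at rest length the force vanishes
  net0 <- two_particle_network(r = 10, d_ij = 10)
  f0 <- elastic_forces(net0$points, net0, p)
  expect_equal(unlist(f0[c("fx", "fy")]), rep(0, 4), ignore_attr = TRUE)
})

test_that("elastic forces equal minus the numerical energy gradient", {
  net <- small_network(n = 40, seed = 5)
  p <- sim_params(k_tilde = 7, b_tilde = 3)
  st <- net$points
  withr::with_seed(2, {
    st$x_um <- st$x_um + rnorm(nrow(st), sd = 2)
    st$y_um <- st$y_um + rnorm(nrow(st), sd = 2)
  })
  f <- elastic_forces(st, net, p)
  h <- 1e-4
  for (i in c(1, 7, 23)) {
    for (dim in c("x_um", "y_um")) {
      up <- st; up[[dim]][i] <- up[[dim]][i] + h
      dn <- st; dn[[dim]][i] <- dn[[dim]][i] - h
      grad <- (elastic_energy(up, net, p) - elastic_energy(dn, net, p)) / (2 * h)
      got <- if (dim == "x_um") f$fx[i] else f$fy[i]
      expect_equal(got, -grad, tolerance = 1e-6)
    }
  }
  # Newton's third law
  scale <- mean(sqrt(f$fx^2 + f$fy^2))
  expect_lt(abs(sum(f$fx)) / scale, 1e-9)
  expect_lt(abs(sum(f$fy)) / scale, 1e-9)
})

test_that("a free particle travels at the propulsion speed", {
  net <- free_particle_network()
  p <- sim_params(k_tilde = 0, b_tilde = 0, dt = 0.01)
  run <- simulate_aes(net, p, duration = 1, snapshot_every = 0.5,
                      confine = FALSE, initial_polarity = matrix(c(1, 0), 1))
  last <- run$snapshots[run$snapshots$frame == max(run$snapshots$frame), ]
  expect_equal(last$x_um, 35, tolerance = 1e-12)
  expect_equal(last$y_um, 0)
  expect_equal(sqrt(last$vx_umph^2 + last$vy_umph^2), 35, tolerance = 1e-12)
})

test_that("polarity dynamics honor the cross-product identities", {
  st <- tibble::tibble(id = 1:2, x_um = c(0, 100), y_um = c(0, 0),
                       px = c(1, 0), py = c(0, 1))
  # gamma = 0 freezes the polarity
  p0 <- sim_params(k_tilde = 0, gamma_tilde = 0, dt = 0.01)
  out <- aes_step(st, NULL, p0)
  expect_equal(out$px, st$px)
  expect_equal(out$py, st$py)
  # P parallel to Rdot: (P x Rdot) x P = 0, polarity unchanged
  p1 <- sim_params(k_tilde = 0, gamma_tilde = 1.5, dt = 0.01)
  out1 <- aes_step(st, NULL, p1)
  expect_equal(out1$px, st$px, tolerance = 1e-12)
  expect_equal(out1$py, st$py, tolerance = 1e-12)
})

test_that("polarities stay unit length through a run", {
  net <- small_network(n = 200, seed = 4)
  run <- simulate_aes(net, sim_params(seed = 8), duration = 0.5,
                      snapshot_every = 0.1)
  norm <- sqrt(run$snapshots$px^2 + run$snapshots$py^2)
  expect_true(all(abs(norm - 1) < 1e-9))
})

test_that("boundary terms are a half-open inward spring plus torque", {
  p <- sim_params(d = 22.5)
  p$boundary_stiffness <- 1
  R <- 100
  st <- tibble::tibble(id = 1:3,
                       x_um = c(R - 22.5, R, R + 5), y_um = c(0, 0, 0),
                       px = c(0, 1, 0.6), py = c(1, 0, 0.8))
  bt <- boundary_terms(st, p, R)
  expect_equal(bt$fx[1:2], c(0, 0))          # interior and exactly-on-boundary
  expect_equal(bt$fx[3], -5)                 # linear inward spring
  expect_equal(bt$fy[3], 0)
  # outward-pointing polarity in the boundary strip is turned, interior is not
  expect_equal(bt$dpx[1], 0)
  expect_lt(bt$dpx[3], 0)
})

test_that("without propulsion the dynamics descend the elastic energy", {
  net <- small_network(n = 200, seed = 4)
  p <- sim_params(v_c = 0, gamma_tilde = 0, dt = 0.002)
  p$k <- 40 * 35 / 22.5                     # keep the spring scale despite v_c = 0
  st <- net$points
  withr::with_seed(3, {
    st$x_um <- st$x_um + rnorm(nrow(st), sd = 3)
    st$y_um <- st$y_um + rnorm(nrow(st), sd = 3)
  })
  pol <- matrix(c(1, 0), nrow(st), 2, byrow = TRUE)
  state <- tibble::tibble(id = st$id, x_um = st$x_um, y_um = st$y_um,
                          px = pol[, 1], py = pol[, 2])
  e_prev <- elastic_energy(state, net, p)
  for (k in 1:20) {
    state <- aes_step(state, net, p)
    e <- elastic_energy(state, net, p)
    expect_lte(e, e_prev + 1e-9 * abs(e_prev))
    e_prev <- e
  }
})

test_that("runs are deterministic and flag unstable time steps", {
  net <- small_network(n = 200, seed = 4)
  r1 <- simulate_aes(net, sim_params(seed = 5), duration = 0.3,
                     snapshot_every = 0.1)
  r2 <- simulate_aes(net, sim_params(seed = 5), duration = 0.3,
                     snapshot_every = 0.1)
  expect_identical(r1$snapshots, r2$snapshots)
  expect_error(
    simulate_aes(net, sim_params(seed = 5, dt = 0.05), duration = 0.3,
                 snapshot_every = 0.1),
    "reduce dt")
})

test_that("halving the time step barely changes the polar order", {
  net <- small_network(n = 200, seed = 4)
  phi <- sapply(c(0.002, 0.001), function(dt) {
    run <- simulate_aes(net, sim_params(seed = 6, dt = dt), duration = 2,
                        snapshot_every = 2, confine = FALSE)
    polar_order(run$snapshots[run$snapshots$frame == max(run$snapshots$frame), ])
  })
  expect_lt(abs(phi[1] - phi[2]) / phi[2], 0.02)
})

test_that("alignment drives polar order in an unconfined monolayer", {
  # at the alignment rate gamma_tilde V_c / d ~ 2.3/h an unconfined
  # 2000-cell blob orders over roughly two coarsening times (~15 h)
  net <- small_network(n = 2000, seed = 7)
  run <- simulate_aes(net, sim_params(seed = 9), duration = 16,
                      snapshot_every = 4, confine = FALSE)
  phis <- sapply(split(run$snapshots, run$snapshots$frame), polar_order)
  expect_lt(phis[1], 0.1)
  expect_gt(tail(phis, 1), 0.7)
  expect_true(all(diff(phis) > -0.05))       # steady rise, no collapse
})
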