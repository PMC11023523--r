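# shared fixtures, built once per test run

fixture_env <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (!exists(key, envir = fixture_env)) {
    assign(key, force(expr), envir = fixture_env)
  }
  get(key, envir = fixture_env)
}

# a small packed network reused by several files
small_network <- function(n = 1500, seed = 7) {
  memo(sprintf("net_%d_%d", n, seed), {
    spec <- lattice_spec(n = n, d = 22.5, seed = seed)
    build_network(pack_disks(spec), spec)
  })
}

# hand-built two-particle network for analytic force checks
two_particle_network <- function(r = 12, d_ij = 10) {
  structure(
    list(points = tibble::tibble(id = 1:2, x_um = c(0, r), y_um = c(0, 0)),
         springs = tibble::tibble(i = 1L, j = 2L, rest_length_um = d_ij),
         spec = lattice_spec(n = 2, d = d_ij, domain_radius = 100, seed = 1)),
    class = "spring_network")
}

# single free particle (no springs)
free_particle_network <- function() {
  structure(
    list(points = tibble::tibble(id = 1L, x_um = 0, y_um = 0),
         springs = tibble::tibble(i = integer(), j = integer(),
                                  rest_length_um = double()),
         spec = lattice_spec(n = 1, d = 22.5, domain_radius = 1e6, seed = 1)),
    class = "spring_network")
}

# confined coarsening runs shared by the acceptance tests (5 seeds, 6 h --
# the full disorder -> defect-rich -> single-vortex cycle completes well
# within the window at this size)
coarsening_runs <- function(seeds = 1:5, n = 4000, duration = 6) {
  memo("coarsening_runs", {
    lapply(seeds, function(s) {
      run_pipeline(run_config(n = n, duration = duration,
                              snapshot_every = 1 / 15, seed = s),
                   keep_fields = TRUE)
    })
  })
}

# independent winding oracle: total direction change along an anticlockwise
# rectangular grid loop (brute force, straight from the definition)
loop_winding <- function(field, ix_range, iy_range) {
  g <- defectflow:::field_grid_of(field)
  fm <- defectflow:::field_matrices(field, g)
  ix <- range(ix_range); iy <- range(iy_range)
  path <- rbind(
    cbind(ix[1]:ix[2], iy[1]),
    cbind(ix[2], (iy[1] + 1):iy[2]),
    cbind((ix[2] - 1):ix[1], iy[2]),
    cbind(ix[1], (iy[2] - 1):(iy[1] + 1))
  )
  th <- atan2(fm$v[path], fm$u[path])
  d <- diff(c(th, th[1]))
  d <- d + 2 * pi * (d < -pi) - 2 * pi * (d > pi)
  round(sum(d) / (2 * pi))
}

expect_tbl_equal <- function(a, b, tol = 1e-12) {
  expect_equal(as.data.frame(a), as.data.frame(b), tolerance = tol)
}

# reversal angles over every called annihilation, extending seeds until at
# least `target` events are collected; extension runs stop at 2.5 h because
# pair annihilations all occur during the early coarsening phase
reversal_harvest <- function(target = 10, max_seeds = 22) {
  memo("reversal_harvest", {
    harvest <- function(res) {
      annihilation_reversals(res$tracks, res$events, res$fields,
                             isolation_radius = 0,
                             dipole_check = FALSE)$reversal_deg
    }
    angles <- unlist(lapply(coarsening_runs(), harvest))
    seed <- length(coarsening_runs())
    while (length(angles) < target && seed < max_seeds) {
      seed <- seed + 1
      res <- run_pipeline(run_config(n = 4000, duration = 2.5,
                                     snapshot_every = 1 / 15, seed = seed),
                          keep_fields = TRUE)
      angles <- c(angles, harvest(res))
    }
    angles
  })
}

# empirical recovery of the same-charge merging threshold: bisection on
# two-vortex fields over a 2-um lattice (centers on half-offset nodes so the
# detected positions track the planted separation exactly)
merge_threshold_bisect <- function(lo = 50, hi = 400, spacing = 2) {
  g <- field_grid(320, 40, spacing)
  y0 <- g$ys[20] + spacing / 2
  x1 <- g$xs[80]
  n_at <- function(sep) {
    f <- compose_defect_field(
      dplyr::bind_rows(defect_spec(x1, y0, 1, pi / 2),
                       defect_spec(x1 + sep, y0, 1, pi / 2)), g)
    nrow(detect_frame(f))
  }
  lo <- lo - lo %% spacing; hi <- hi - hi %% spacing
  stopifnot(n_at(lo) == 1, n_at(hi) == 2)
  while (hi - lo > spacing) {
    mid <- lo + (round((hi - lo) / (2 * spacing))) * spacing
    if (n_at(mid) == 1) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}
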