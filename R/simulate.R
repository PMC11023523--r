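#' Parameters of the active elastic solid model
#'
#' The model couples overdamped self-propulsion to network elasticity:
#' positions obey `Rdot_i = V_c P_i + F_i / zeta` and the unit polarity
#' turns toward the instantaneous velocity, `Pdot_i = gamma (P_i x Rdot_i) x P_i`.
#' Two dimensionless groups control the physics: the rigidity
#' `K_tilde = K d / (zeta V_c)` and the turning rate `gamma_tilde = gamma d`
#' (time measured in units of d / V_c, so the alignment rate is
#' `gamma_tilde V_c / d` per hour). The quartic spring coefficient is set
#' by `b_tilde = B d^3 / (zeta V_c)`; its default `k_tilde / 4` makes the
#' nonlinear term equal the harmonic one at 50% strain and negligible below
#' 20% strain.
#'
#' The substrate friction `zeta` is fixed at 1 and defines the force unit.
#' The default time step is set from the stiffest rate in the system: spring
#' relaxation (`K * degree / zeta`), polarity turning (`gamma * V_c`) and the
#' advective limit `V_c dt <= 0.05 d`.
#'
#' @param v_c Propulsion speed in um/h (default 35).
#' @param k_tilde Dimensionless spring constant (default 40).
#' @param gamma_tilde Dimensionless turning rate (default 1.5).
#' @param b_tilde Dimensionless quartic coefficient (default `k_tilde / 4`).
#' @param d Mean cell spacing in um used for the nondimensionalization.
#' @param zeta Substrate friction (force h / um); 1 defines the force unit.
#' @param dt Time step in hours; default derived from the stability limits.
#' @param boundary_stiffness Spring constant of the confinement force
#'   (force / um) acting on particles outside the domain radius.
#' @param boundary_turn_rate Rate (1/h) at which polarity turns toward the
#'   inward normal near the boundary.
#' @param boundary_turn_zone Width of the boundary strip (um) in which the
#'   polarity turning acts (default `d/2`).
#' @param seed RNG seed for the initial polarity draw.
#' @return A list with class `sim_params`; includes the dimensional `k`,
#'   `b`, `gamma` implied by the dimensionless groups.
#' @export
sim_params <- function(v_c = 35, k_tilde = 40, gamma_tilde = 1.5,
                       b_tilde = k_tilde / 4, d = 22.5, zeta = 1,
                       dt = NULL, boundary_stiffness = NULL,
                       boundary_turn_rate = 5, boundary_turn_zone = d / 2,
                       seed = 1L) {
  stopifnot(v_c >= 0, zeta > 0, k_tilde >= 0, b_tilde >= 0,
            gamma_tilde >= 0, d > 0)
  k <- k_tilde * zeta * v_c / d
  b <- b_tilde * zeta * v_c / d^3
  gamma <- gamma_tilde / d                  # units 1/um
  if (is.null(boundary_stiffness)) boundary_stiffness <- max(k, 1)
  if (is.null(dt)) {
    rates <- c(spring = 6 * k / zeta, turning = gamma * 2 * v_c,
               boundary = 6 * boundary_stiffness / zeta)
    dt_stab <- 0.5 / max(rates, 1e-12)
    dt_adv <- if (v_c > 0) 0.05 * d / v_c else Inf
    dt <- min(dt_stab, dt_adv, 0.025)
  }
  stopifnot(dt > 0)
  structure(
    list(v_c = v_c, zeta = zeta, k = k, b = b, gamma = gamma,
         k_tilde = k_tilde, gamma_tilde = gamma_tilde, b_tilde = b_tilde,
         d = d, dt = dt, boundary_stiffness = boundary_stiffness,
         boundary_turn_rate = boundary_turn_rate,
         boundary_turn_zone = boundary_turn_zone, seed = as.integer(seed)),
    class = "sim_params"
  )
}

state_matrices <- function(state) {
  stopifnot(is.data.frame(state), all(c("x_um", "y_um") %in% names(state)))
  pos <- cbind(state$x_um, state$y_um)
  pol <- if (all(c("px", "py") %in% names(state))) cbind(state$px, state$py) else NULL
  list(pos = pos, pol = pol)
}

#' Elastic spring forces on every particle
#'
#' Each spring stores energy `U(r) = K/2 (d_ij - r)^2 + B (d_ij - r)^4`; the
#' force on particle i is minus the gradient of the total energy, i.e. a
#' pair force of magnitude `K (d_ij - r) + 4 B (d_ij - r)^3` along the bond,
#' restoring the rest length.
#'
#' @param state A data frame with columns `x_um`, `y_um` (rows in `id` order).
#' @param network A [build_network()] result.
#' @param params A [sim_params()].
#' @return A tibble with columns `id`, `fx`, `fy` (force units).
#' @export
elastic_forces <- function(state, network, params) {
  pos <- state_matrices(state)$pos
  f <- elastic_forces_mat(pos, network$springs, params)
  tibble::tibble(id = seq_len(nrow(pos)), fx = f[, 1], fy = f[, 2])
}

elastic_forces_mat <- function(pos, springs, params) {
  n <- nrow(pos)
  f <- matrix(0, n, 2)
  if (is.null(springs) || nrow(springs) == 0) return(f)
  i <- springs$i; j <- springs$j
  e <- pos[i, , drop = FALSE] - pos[j, , drop = FALSE]
  r <- sqrt(rowSums(e^2))
  if (any(r <= 0)) {
    bad <- which(r <= 0)[1]
    abort(sprintf("coincident bonded particles on edge (%d, %d)", i[bad], j[bad]))
  }
  s <- springs$rest_length_um - r
  mag <- params$k * s + 4 * params$b * s^3
  pair <- (mag / r) * e                     # force on i along (R_i - R_j)
  acc <- rowsum(rbind(pair, -pair), c(i, j))
  f[as.integer(rownames(acc)), ] <- acc
  f
}

#' Total elastic energy of the network
#'
#' @inheritParams elastic_forces
#' @return Scalar energy (force x um).
#' @export
elastic_energy <- function(state, network, params) {
  pos <- state_matrices(state)$pos
  i <- network$springs$i; j <- network$springs$j
  r <- sqrt(rowSums((pos[i, , drop = FALSE] - pos[j, , drop = FALSE])^2))
  s <- network$springs$rest_length_um - r
  sum(params$k / 2 * s^2 + params$b * s^4)
}

#' Confinement force and polarity turning at the boundary
#'
#' Particles outside the circular domain feel an inward radial spring force
#' `boundary_stiffness * (|R_i| - R)`; particles within `d/2` of the boundary
#' have their polarity rotated toward the inward normal at angular rate
#' `boundary_turn_rate * sin(angle to normal)`. Interior particles are
#' unaffected; a particle exactly on the boundary feels no force.
#'
#' @param state Data frame with `x_um`, `y_um` and (for the torque) `px`, `py`.
#' @param params A [sim_params()].
#' @param domain_radius Radius of the confinement in um.
#' @return A tibble with columns `id`, `fx`, `fy`, `dpx`, `dpy` where
#'   `(dpx, dpy)` is the polarity rate-of-change increment (1/h).
#' @export
boundary_terms <- function(state, params, domain_radius) {
  sm <- state_matrices(state)
  bt <- boundary_terms_mat(sm$pos, sm$pol, params, domain_radius)
  tibble::tibble(id = seq_len(nrow(sm$pos)),
                 fx = bt$f[, 1], fy = bt$f[, 2],
                 dpx = bt$dp[, 1], dpy = bt$dp[, 2])
}

boundary_terms_mat <- function(pos, pol, params, domain_radius) {
  n <- nrow(pos)
  f <- matrix(0, n, 2)
  dp <- matrix(0, n, 2)
  r <- sqrt(rowSums(pos^2))
  out <- r > domain_radius
  if (any(out)) {
    rhat <- pos[out, , drop = FALSE] / r[out]
    f[out, ] <- -params$boundary_stiffness * (r[out] - domain_radius) * rhat
  }
  if (!is.null(pol)) {
    near <- r > domain_radius - params$boundary_turn_zone
    if (any(near)) {
      rhat <- pos[near, , drop = FALSE] / pmax(r[near], 1e-12)
      p <- pol[near, , drop = FALSE]
      # rotate P away from the outward normal, but only while it points
      # outward: tangential and inward orientations are torque-free, so a
      # wall-following (vortex) state is not disturbed
      proj <- rowSums(p * rhat)
      dp[near, ] <- -params$boundary_turn_rate * pmax(proj, 0) *
        (rhat - proj * p)
    }
  }
  list(f = f, dp = dp)
}

#' Advance the state by one explicit Euler step
#'
#' `Rdot_i = V_c P_i + F_i / zeta`, then
#' `P_i <- P_i + gamma [(P_i x Rdot_i) x P_i] dt`, renormalized to unit
#' length. For unit `P` the double cross product equals
#' `Rdot - (P . Rdot) P`, which is how it is evaluated.
#'
#' @param state Data frame with columns `x_um`, `y_um`, `px`, `py`.
#' @param network A [build_network()] result (or `NULL` for free particles).
#' @param params A [sim_params()].
#' @param domain_radius Confinement radius in um, or `NULL` for no boundary.
#' @return A tibble like `state` with updated positions/polarities and the
#'   velocities `vx_umph`, `vy_umph` used for the step.
#' @export
aes_step <- function(state, network = NULL, params = sim_params(),
                     domain_radius = NULL) {
  sm <- state_matrices(state)
  if (is.null(sm$pol)) abort("state must carry unit polarities `px`, `py`")
  st <- step_mat(sm$pos, sm$pol, network$springs, params, domain_radius)
  tibble::tibble(id = seq_len(nrow(st$pos)),
                 x_um = st$pos[, 1], y_um = st$pos[, 2],
                 px = st$pol[, 1], py = st$pol[, 2],
                 vx_umph = st$vel[, 1], vy_umph = st$vel[, 2])
}

step_mat <- function(pos, pol, springs, params, domain_radius) {
  f <- elastic_forces_mat(pos, springs, params)
  dp_b <- 0
  if (!is.null(domain_radius)) {
    bt <- boundary_terms_mat(pos, pol, params, domain_radius)
    f <- f + bt$f
    dp_b <- bt$dp
  }
  vel <- params$v_c * pol + f / params$zeta
  step <- vel * params$dt
  disp <- sqrt(rowSums(step^2))
  if (!all(is.finite(disp))) abort("non-finite positions in integration step")
  if (max(disp) > 0.5 * params$d) {
    abort(sprintf(
      "unstable integration: max displacement %.3g um exceeds 0.5 d = %.3g um; reduce dt",
      max(disp), 0.5 * params$d))
  }
  pos <- pos + step
  proj <- rowSums(pol * vel)
  dp <- params$gamma * (vel - proj * pol) + dp_b
  pol <- pol + dp * params$dt
  norm <- sqrt(rowSums(pol^2))
  if (any(!is.finite(norm)) || any(norm < 1e-12)) {
    abort("polarity renormalization failed (zero or non-finite vector)")
  }
  pol <- pol / norm
  list(pos = pos, pol = pol, vel = vel)
}

#' Run an active elastic solid simulation
#'
#' Integrates the model from a stress-free lattice with i.i.d. uniform random
#' initial polarity angles. Snapshots of positions, polarities and velocities
#' are recorded every `snapshot_every` hours (plus the initial state).
#'
#' @param network A [build_network()] result.
#' @param params A [sim_params()].
#' @param duration Simulated time in hours.
#' @param snapshot_every Snapshot interval in hours.
#' @param confine If `TRUE` (default) apply the circular boundary at the
#'   lattice's domain radius.
#' @param initial_polarity `"random"` (default) or an N x 2 matrix of unit
#'   vectors.
#' @param pre_relax_h Hours of propulsion-free mechanical relaxation before
#'   t = 0 (default 0.25). Rest-length clamping leaves a little residual
#'   stress in the as-built lattice; this settles it so the run starts from
#'   mechanical equilibrium.
#' @return An object of class `aes_run`: list with `snapshots` (tibble:
#'   `frame`, `t_h`, `id`, `x_um`, `y_um`, `px`, `py`, `vx_umph`, `vy_umph`),
#'   `params`, `network`, and `meta` (seed, `k_tilde`, `gamma_tilde`).
#' @export
simulate_aes <- function(network, params = sim_params(), duration,
                         snapshot_every = duration / 20, confine = TRUE,
                         initial_polarity = "random", pre_relax_h = 0.25) {
  stopifnot(inherits(network, "spring_network"), duration > 0, snapshot_every > 0)
  n <- nrow(network$points)
  pos <- cbind(network$points$x_um, network$points$y_um)
  if (identical(initial_polarity, "random")) {
    ang <- with_seed_(params$seed, runif(n, 0, 2 * pi))
    pol <- cbind(cos(ang), sin(ang))
  } else {
    pol <- as.matrix(initial_polarity)
    stopifnot(nrow(pol) == n, ncol(pol) == 2)
    pol <- pol / sqrt(rowSums(pol^2))
  }
  domain_radius <- if (confine) network$spec$domain_radius else NULL
  if (pre_relax_h > 0 && nrow(network$springs) > 0) {
    relax <- params
    relax$v_c <- 0
    relax$gamma <- 0
    relax$boundary_turn_rate <- 0
    for (s in seq_len(ceiling(pre_relax_h / params$dt))) {
      st <- step_mat(pos, pol, network$springs, relax, domain_radius)
      pos <- st$pos
    }
  }
  n_steps <- ceiling(duration / params$dt)
  every <- max(1L, round(snapshot_every / params$dt))
  vel0 <- params$v_c * pol +
    elastic_forces_mat(pos, network$springs, params) / params$zeta
  snaps <- list(snapshot_tbl(1L, 0, pos, pol, vel0))
  fr <- 1L
  for (s in seq_len(n_steps)) {
    st <- step_mat(pos, pol, network$springs, params, domain_radius)
    pos <- st$pos; pol <- st$pol
    if (s %% every == 0 || s == n_steps) {
      fr <- fr + 1L
      snaps[[fr]] <- snapshot_tbl(fr, s * params$dt, pos, pol, st$vel)
    }
  }
  structure(
    list(snapshots = dplyr::bind_rows(snaps), params = params, network = network,
         meta = list(seed = params$seed, k_tilde = params$k_tilde,
                     gamma_tilde = params$gamma_tilde, b_tilde = params$b_tilde,
                     dt = params$dt, duration = duration, confined = confine)),
    class = "aes_run"
  )
}

snapshot_tbl <- function(frame, t_h, pos, pol, vel) {
  tibble::tibble(frame = frame, t_h = t_h, id = seq_len(nrow(pos)),
                 x_um = pos[, 1], y_um = pos[, 2],
                 px = pol[, 1], py = pol[, 2],
                 vx_umph = vel[, 1], vy_umph = vel[, 2])
}

#' Polar order parameter of a snapshot
#'
#' `phi = |sum_i P_i| / N`: 0 for disordered polarity, 1 for perfect
#' alignment.
#'
#' @param snapshot A data frame with columns `px`, `py` (one frame).
#' @return Scalar in `[0, 1]`.
#' @export
polar_order <- function(snapshot) {
  sqrt(mean(snapshot$px)^2 + mean(snapshot$py)^2)
}

#' @export
print.aes_run <- function(x, ...) {
  nf <- length(unique(x$snapshots$frame))
  cat(sprintf(
    "<aes_run> N = %d, K~ = %.3g, gamma~ = %.3g, dt = %.4g h, %d frames over %.3g h%s\n",
    nrow(x$network$points), x$params$k_tilde, x$params$gamma_tilde,
    x$params$dt, nf, x$meta$duration, if (x$meta$confined) ", confined" else ""))
  invisible(x)
}
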