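#' Specify a disordered bead-spring lattice
#'
#' The monolayer is represented mechanically as beads (cells) connected by
#' springs. The lattice is deliberately disordered -- no long-range hexagonal
#' order -- so that the elastic response is globally isotropic. `domain_radius`
#' defaults to the radius at which the packed, Voronoi-connected network
#' realizes a mean spring rest length of `d` (area 0.932 d^2 per cell,
#' about 3.8 mm for 100,000 cells at d = 22.5 um).
#'
#' @param n Target number of cells (>= 3 for a network; n >= 1 for packing).
#' @param d Mean cell spacing in micrometers (default 22.5).
#' @param domain_radius Radius of the circular domain in micrometers.
#' @param polydispersity Two-element interval of rest-length factors
#'   (default `c(0.8, 1.2)`); spring rest lengths are confined to
#'   `polydispersity * d`.
#' @param seed Integer RNG seed recorded in the output metadata.
#' @return A list with class `lattice_spec`.
#' @export
lattice_spec <- function(n = 100000, d = 22.5,
                         domain_radius = default_domain_radius(n, d),
                         polydispersity = c(0.8, 1.2), seed = 1L) {
  if (!(n >= 1)) abort("`n` must be at least 1")
  if (!(d > 0)) abort("`d` must be positive")
  if (!(domain_radius > 0)) abort("`domain_radius` must be positive")
  if (length(polydispersity) != 2 || any(polydispersity <= 0) ||
      polydispersity[1] >= polydispersity[2]) {
    abort("`polydispersity` must be an increasing positive interval")
  }
  structure(
    list(n = as.integer(n), d = as.double(d),
         domain_radius = as.double(domain_radius),
         polydispersity = as.double(polydispersity), seed = as.integer(seed)),
    class = "lattice_spec"
  )
}

#' @rdname lattice_spec
#' @export
default_domain_radius <- function(n, d = 22.5) d * sqrt(0.932 * n / pi)

# run code under a temporary RNG state seeded with `seed` (NULL = use current)
with_seed_ <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

#' Pack repulsive disks into the circular domain
#'
#' Places `n` differently sized repulsive disks by random insertion at 60% of
#' their target radius followed by iterative radius growth with
#' overlap-relaxation and Metropolis-style kick moves. The result is a
#' statistically isotropic point set whose nearest-neighbor spacing
#' distribution has mean close to `d`, without long-range crystalline order.
#'
#' @param spec A [lattice_spec()].
#' @return A tibble with columns `id`, `x_um`, `y_um`.
#' @export
pack_disks <- function(spec) {
  stopifnot(inherits(spec, "lattice_spec"))
  n <- spec$n; d <- spec$d; R <- spec$domain_radius
  # even a hexagonal packing at the lower polydispersity bound must fit
  if (n * (spec$polydispersity[1] * d)^2 * sqrt(3) / 2 > pi * R^2) {
    abort(sprintf(
      "infeasible density: %d disks of diameter >= %.3g um cannot pack into radius %.3g um",
      n, spec$polydispersity[1] * d, R))
  }
  with_seed_(spec$seed, {
    pos <- random_points_in_disk(n, R)
    if (n < 2) {
      return(tibble::tibble(id = seq_len(n), x_um = pos[, 1], y_um = pos[, 2]))
    }
    fac <- runif(n, spec$polydispersity[1], spec$polydispersity[2])
    rho <- fac * d / 2                       # target disk radii
    scales <- 0.6 * 1.06^(0:9)
    scales <- c(pmin(scales, 1), 1)
    # one relaxation sweep per growth stage: enough to resolve overlaps,
    # little enough to avoid annealing local hexatic patches
    for (s in unique(scales)) {
      pos <- relax_overlaps(pos, rho * s, R, d)
      pos <- metropolis_kicks(pos, rho * s, R, d)
    }
    tibble::tibble(id = seq_len(n), x_um = pos[, 1], y_um = pos[, 2])
  })
}

random_points_in_disk <- function(n, R) {
  r <- R * sqrt(runif(n))
  a <- runif(n, 0, 2 * pi)
  cbind(r * cos(a), r * sin(a))
}

# candidate close pairs via a fixed-radius neighbor search
close_pairs <- function(pos, cutoff) {
  k <- min(nrow(pos) - 1L, 12L)
  nn <- FNN::get.knn(pos, k = k)
  i <- rep(seq_len(nrow(pos)), k)
  j <- as.vector(nn$nn.index)
  dist <- as.vector(nn$nn.dist)
  keep <- i < j & dist < cutoff
  list(i = i[keep], j = j[keep], dist = dist[keep])
}

relax_overlaps <- function(pos, rho, R, d) {
  cp <- close_pairs(pos, cutoff = max(rho) * 2)
  target <- rho[cp$i] + rho[cp$j]
  ov <- target - cp$dist
  hit <- ov > 0
  if (any(hit)) {
    i <- cp$i[hit]; j <- cp$j[hit]
    dvec <- pos[j, , drop = FALSE] - pos[i, , drop = FALSE]
    len <- pmax(cp$dist[hit], 1e-9 * d)
    push <- 0.45 * ov[hit] / len * dvec
    dx <- rowsum(rbind(-push, push), c(i, j))
    idx <- as.integer(rownames(dx))
    pos[idx, ] <- pos[idx, ] + dx
  }
  clamp_to_disk(pos, R, margin = 0)
}

# random kick moves for still-overlapping disks, accepted when they reduce
# the local overlap energy (zero-temperature Metropolis)
metropolis_kicks <- function(pos, rho, R, d) {
  ov <- overlap_energy(pos, rho, d)
  bad <- which(ov > 0)
  if (!length(bad)) return(pos)
  prop <- pos
  prop[bad, ] <- prop[bad, ] + matrix(rnorm(2 * length(bad), sd = 0.05 * d), ncol = 2)
  prop <- clamp_to_disk(prop, R, margin = 0)
  ov2 <- overlap_energy(prop, rho, d)
  accept <- bad[ov2[bad] < ov[bad]]
  pos[accept, ] <- prop[accept, ]
  pos
}

overlap_energy <- function(pos, rho, d) {
  cp <- close_pairs(pos, cutoff = max(rho) * 2)
  ov <- pmax(rho[cp$i] + rho[cp$j] - cp$dist, 0)
  e <- numeric(nrow(pos))
  if (length(ov)) {
    acc <- rowsum(c(ov^2, ov^2), c(cp$i, cp$j))
    e[as.integer(rownames(acc))] <- acc[, 1]
  }
  e
}

clamp_to_disk <- function(pos, R, margin = 0) {
  r <- sqrt(rowSums(pos^2))
  out <- r > R - margin
  if (any(out)) {
    sc <- (R - margin) / r[out]
    pos[out, ] <- pos[out, ] * sc
  }
  pos
}

#' Build the spring network by Voronoi tessellation
#'
#' Springs connect Voronoi-adjacent (Delaunay-neighbor) cell pairs. Sliver
#' edges along the convex hull (longer than `1.5 d`) are pruned, and rest
#' lengths are the initial inter-point distances clamped to the
#' polydispersity interval, which leaves the initial state stress-free
#' wherever no clamping occurs.
#'
#' @param points A tibble with columns `id`, `x_um`, `y_um` (e.g. from
#'   [pack_disks()]).
#' @param spec The [lattice_spec()] used to generate the points.
#' @return A list with class `spring_network`: `points`, `springs`
#'   (columns `i`, `j`, `rest_length_um`), and `spec`.
#' @export
build_network <- function(points, spec) {
  stopifnot(is.data.frame(points), all(c("x_um", "y_um") %in% names(points)))
  n <- nrow(points)
  if (n < 3) abort("need at least 3 points to triangulate")
  x <- points$x_um; y <- points$y_um
  if (abs(max(x) - min(x)) < 1e-12 || is_collinear(x, y)) {
    abort("points are collinear or coincident; cannot build a planar network")
  }
  # break exact cocircular ties before tessellation
  eps <- 1e-6 * spec$d
  xp <- x + with_seed_(spec$seed + 1L, runif(n, -eps, eps))
  yp <- y + with_seed_(spec$seed + 1L, runif(2 * n, -eps, eps)[(n + 1):(2 * n)])
  dd <- deldir::deldir(xp, yp, suppressMsge = TRUE)
  i <- pmin(dd$delsgs$ind1, dd$delsgs$ind2)
  j <- pmax(dd$delsgs$ind1, dd$delsgs$ind2)
  keep <- !duplicated(cbind(i, j)) & i != j
  i <- i[keep]; j <- j[keep]
  len <- sqrt((x[i] - x[j])^2 + (y[i] - y[j])^2)
  if (any(len < 1e-9 * spec$d)) abort("duplicate points detected; cannot assign springs")
  # boundary pruning: drop hull slivers, but never disconnect the graph
  long <- len > 1.5 * spec$d
  if (any(long)) {
    ord <- order(len)                     # consider edges short-to-long
    keep_edge <- !long
    comp <- components_of(n, i[keep_edge], j[keep_edge])
    if (max(comp) > 1) {
      for (e in ord[long[ord]]) {
        if (comp[i[e]] != comp[j[e]]) {
          keep_edge[e] <- TRUE
          comp[comp == comp[j[e]]] <- comp[i[e]]
          if (length(unique(comp)) == 1) break
        }
      }
    }
    i <- i[keep_edge]; j <- j[keep_edge]; len <- len[keep_edge]
  }
  lo <- spec$polydispersity[1] * spec$d
  hi <- spec$polydispersity[2] * spec$d
  structure(
    list(
      points = tibble::tibble(id = seq_len(n), x_um = x, y_um = y),
      springs = tibble::tibble(i = as.integer(i), j = as.integer(j),
                               rest_length_um = pmin(pmax(len, lo), hi)),
      spec = spec
    ),
    class = "spring_network"
  )
}

is_collinear <- function(x, y) {
  x <- x - mean(x); y <- y - mean(y)
  m <- cbind(x, y)
  sv <- svd(m, nu = 0, nv = 0)$d
  sv[2] < 1e-10 * max(sv[1], 1)
}

# connected components by label propagation (small helper; avoids a graph dep)
components_of <- function(n, i, j) {
  comp <- seq_len(n)
  repeat {
    a <- pmin(comp[i], comp[j])
    new_i <- pmin(comp[i], a); new_j <- pmin(comp[j], a)
    ch <- FALSE
    m <- tapply(c(new_i, new_j), c(i, j), min)
    idx <- as.integer(names(m))
    upd <- comp[idx] > m
    if (any(upd)) {
      comp[idx[upd]] <- m[upd]
      ch <- TRUE
    }
    # propagate until stable
    if (!ch) break
  }
  # compress labels
  match(comp, sort(unique(comp)))
}

#' @export
print.spring_network <- function(x, ...) {
  cat(sprintf("<spring_network> %d points, %d springs, d = %.3g um, R = %.4g um\n",
              nrow(x$points), nrow(x$springs), x$spec$d, x$spec$domain_radius))
  cat(sprintf("  rest lengths: mean %.4g um, range [%.4g, %.4g] um\n",
              mean(x$springs$rest_length_um), min(x$springs$rest_length_um),
              max(x$springs$rest_length_um)))
  invisible(x)
}
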