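#' @name synth
#' @title Seeded generators of synthetic benchmark datasets
#'
#' @description
#' Generators for the point-cloud families used to validate principal graph
#' learning: branching clouds built from parabolic arcs in a unit hypercube
#' (each new branch starting from a random point of a previous branch in a
#' random direction), arm-star clouds with a single known junction, a circle
#' joined to a branching arc, intersecting planar curves (the "travel maze"
#' setting), and uniform background noise. Every generator is a pure
#' function of its arguments and seed, and returns ground-truth labels and
#' curves for topology-recovery checks.
NULL

random_orthonormal_pair <- function(m) {
  u <- stats::rnorm(m)
  u <- u / sqrt(sum(u^2))
  v <- stats::rnorm(m)
  v <- v - sum(v * u) * u
  nv <- sqrt(sum(v^2))
  if (nv < 1e-12) return(random_orthonormal_pair(m))
  list(u = u, v = v / nv)
}

# parabolic arc t in [0,1]: P(t) = root + (L t) u + curvature (L t)^2 v
make_arc <- function(root, u, v, len, curvature) {
  force(root); force(u); force(v); force(len); force(curvature)
  function(t) {
    s <- len * t
    outer(s, u) + outer(curvature * s^2, v) +
      matrix(root, length(t), length(root), byrow = TRUE)
  }
}

arc_table <- function(curve, n_grid = 200L) {
  t <- seq(0, 1, length.out = n_grid)
  P <- curve(t)
  seg <- sqrt(rowSums(diff(P)^2))
  list(t = t, s = c(0, cumsum(seg)), length = sum(seg))
}

# draw t values giving (approximately) arc-length-uniform samples
sample_arc_uniform <- function(curve, n) {
  tab <- arc_table(curve)
  s <- stats::runif(n, 0, tab$length)
  stats::approx(tab$s, tab$t, xout = s, rule = 2L)$y
}

#' Generate a branching point cloud from parabolic arcs
#'
#' Builds `n_branches` parabolic arcs inside the unit hypercube: the first
#' arc starts at a random interior point in a random direction; every
#' subsequent arc is rooted at a uniformly drawn arc-length point of a
#' previously generated arc, again in a random direction. Points are sampled
#' uniformly along each arc, perturbed by isotropic Gaussian noise of s.d.
#' `sigma`, and clipped to the hypercube. Optionally a fraction of uniform
#' background noise is appended.
#'
#' @param n_points total number of on-structure points.
#' @param dim ambient dimension m (each arc lives in a random 2D subspace).
#' @param n_branches number of arcs.
#' @param curvature parabolic coefficient of the arcs.
#' @param sigma isotropic Gaussian noise s.d. around the arcs.
#' @param noise_fraction fraction of the returned points that is uniform
#'   background noise, in \[0, 1).
#' @param seed integer seed.
#' @return list with `X` (points), `labels` (branch id per point, 0 for
#'   background noise), `curves` (list of arc functions of t in \[0, 1\]),
#'   `junctions` (matrix of branch root points, one per arc after the
#'   first), and `noise_mask`.
#' @export
generate_branching <- function(n_points = 300L, dim = 3L, n_branches = 4L,
                               curvature = 1, sigma = 0.02,
                               noise_fraction = 0, seed = 1L) {
  stopifnot(n_points >= n_branches, dim >= 2L, n_branches >= 1L,
            sigma >= 0, noise_fraction >= 0, noise_fraction < 1)
  set.seed(seed)
  curves <- vector("list", n_branches)
  junctions <- matrix(numeric(0), 0L, dim)
  for (b in seq_len(n_branches)) {
    if (b == 1L) {
      root <- stats::runif(dim, 0.25, 0.75)
    } else {
      parent <- sample.int(b - 1L, 1L)
      t0 <- sample_arc_uniform(curves[[parent]], 1L)
      root <- as.numeric(curves[[parent]](t0))
      junctions <- rbind(junctions, root)
    }
    ons <- random_orthonormal_pair(dim)
    len <- stats::runif(1L, 0.25, 0.6)
    curves[[b]] <- make_arc(root, ons$u, ons$v, len, curvature)
  }
  sizes <- rep(n_points %/% n_branches, n_branches)
  extra <- n_points - sum(sizes)
  if (extra > 0L) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
  X <- NULL
  labels <- integer(0)
  for (b in seq_len(n_branches)) {
    t <- sample_arc_uniform(curves[[b]], sizes[b])
    P <- curves[[b]](t) + matrix(stats::rnorm(sizes[b] * dim, sd = sigma),
                                 sizes[b], dim)
    X <- rbind(X, P)
    labels <- c(labels, rep(b, sizes[b]))
  }
  X <- pmin(pmax(X, 0), 1)
  noise_mask <- rep(FALSE, nrow(X))
  if (noise_fraction > 0) {
    ns <- add_background_noise(X, noise_fraction, seed = seed + 1L)
    X <- ns$X
    labels <- c(labels, rep(0L, sum(ns$noise_mask)))
    noise_mask <- ns$noise_mask
  }
  rownames(X) <- NULL
  list(X = X, labels = labels, curves = curves, junctions = junctions,
       noise_mask = noise_mask)
}

#' Generate an n-armed star point cloud
#'
#' Arms radiate from a common centre at evenly spaced angles (in a random 2D
#' subspace of the ambient space), with mild parabolic bending, so the
#' ground truth has exactly one junction of degree `n_arms`.
#'
#' @param n_points total number of points.
#' @param dim ambient dimension.
#' @param n_arms number of arms (>= 3 gives a branching structure).
#' @param arm_length arm length as fraction of the hypercube side.
#' @param curvature parabolic bending of the arms.
#' @param sigma Gaussian noise s.d.
#' @param seed integer seed.
#' @return list with `X`, `labels` (arm id per point), `center`, and
#'   `curves`.
#' @export
generate_armed_star <- function(n_points = 300L, dim = 2L, n_arms = 3L,
                                arm_length = 0.35, curvature = 0.3,
                                sigma = 0.02, seed = 1L) {
  stopifnot(n_arms >= 2L, dim >= 2L)
  set.seed(seed)
  center <- rep(0.5, dim)
  ons <- random_orthonormal_pair(dim)
  angles <- 2 * pi * (seq_len(n_arms) - 1L) / n_arms +
    stats::runif(1L, 0, 2 * pi / n_arms)
  curves <- vector("list", n_arms)
  for (a in seq_len(n_arms)) {
    u <- cos(angles[a]) * ons$u + sin(angles[a]) * ons$v
    v <- -sin(angles[a]) * ons$u + cos(angles[a]) * ons$v
    curves[[a]] <- make_arc(center, u, v, arm_length, curvature)
  }
  sizes <- rep(n_points %/% n_arms, n_arms)
  extra <- n_points - sum(sizes)
  if (extra > 0L) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
  X <- NULL
  labels <- integer(0)
  for (a in seq_len(n_arms)) {
    t <- sample_arc_uniform(curves[[a]], sizes[a])
    P <- curves[[a]](t) + matrix(stats::rnorm(sizes[a] * dim, sd = sigma),
                                 sizes[a], dim)
    X <- rbind(X, P)
    labels <- c(labels, rep(a, sizes[a]))
  }
  X <- pmin(pmax(X, 0), 1)
  rownames(X) <- NULL
  list(X = X, labels = labels, center = center, curves = curves)
}

#' Append uniform background noise to a dataset
#'
#' Adds `ceiling(fraction / (1 - fraction) * N)` points drawn uniformly over
#' the bounding box of `X`, so that the requested fraction of the returned
#' points is noise.
#'
#' @param X data matrix.
#' @param fraction desired noise fraction of the output, in \[0, 1).
#' @param seed integer seed.
#' @return list with `X` (signal rows first, then noise) and `noise_mask`.
#' @export
add_background_noise <- function(X, fraction, seed = 1L) {
  X <- as.matrix(X)
  stopifnot(fraction >= 0, fraction < 1)
  N <- nrow(X)
  if (fraction == 0)
    return(list(X = X, noise_mask = rep(FALSE, N)))
  set.seed(seed)
  n_noise <- ceiling(fraction / (1 - fraction) * N)
  rng <- apply(X, 2L, range)
  noise <- vapply(seq_len(ncol(X)), function(j)
    stats::runif(n_noise, rng[1L, j], rng[2L, j]), numeric(n_noise))
  noise <- matrix(noise, nrow = n_noise)
  list(X = rbind(X, noise),
       noise_mask = c(rep(FALSE, N), rep(TRUE, n_noise)))
}

#' Generate a circle joined to a branching arc
#'
#' A planar circle plus a parabolic branch attached to a point of the
#' circle and heading outward - the simplest non-tree topology combined
#' with a branch.
#'
#' @param n_points total number of points.
#' @param radius circle radius.
#' @param branch_length length of the attached arc.
#' @param sigma Gaussian noise s.d.
#' @param seed integer seed.
#' @return list with `X` (2D), `labels` (1 = circle, 2 = branch), `center`,
#'   `radius`, and `attach_point`.
#' @export
generate_circle_branch <- function(n_points = 300L, radius = 0.25,
                                   branch_length = 0.3, sigma = 0.01,
                                   seed = 1L) {
  set.seed(seed)
  center <- c(0.45, 0.5)
  n_circle <- ceiling(2 / 3 * n_points)
  n_branch <- n_points - n_circle
  theta <- stats::runif(n_circle, 0, 2 * pi)
  Xc <- cbind(center[1L] + radius * cos(theta),
              center[2L] + radius * sin(theta))
  attach_theta <- 0
  attach <- center + radius * c(cos(attach_theta), sin(attach_theta))
  arc <- make_arc(attach, c(1, 0), c(0, 1), branch_length, 0.8)
  t <- sample_arc_uniform(arc, n_branch)
  Xb <- arc(t)
  X <- rbind(Xc, Xb) + matrix(stats::rnorm(2L * n_points, sd = sigma),
                              n_points, 2L)
  X <- pmin(pmax(X, 0), 1)
  rownames(X) <- NULL
  list(X = X, labels = c(rep(1L, n_circle), rep(2L, n_branch)),
       center = center, radius = radius, attach_point = attach)
}

#' Generate intersecting planar curves (the "travel maze" setting)
#'
#' Three smooth curves crossing each other repeatedly in the unit square,
#' uniformly sampled along their length, with curve labels. The family is
#' fixed (sinusoidal threads of different frequency and phase) so that at
#' least two pairwise intersection points are guaranteed; the intersection
#' count is computed and returned.
#'
#' @param n_per_curve points per curve.
#' @param n_curves number of curves (2 or 3).
#' @param sigma Gaussian noise s.d.
#' @param seed integer seed.
#' @return list with `X`, `labels`, `curve_funs` (y as a function of x), and
#'   `n_intersections` (total over curve pairs).
#' @export
generate_intersecting_curves <- function(n_per_curve = 150L, n_curves = 3L,
                                         sigma = 0.01, seed = 1L) {
  stopifnot(n_curves >= 2L, n_curves <= 3L)
  set.seed(seed)
  funs <- list(
    function(x) 0.5 + 0.30 * sin(2 * pi * x),
    function(x) 0.5 - 0.30 * sin(2 * pi * x),
    function(x) 0.5 + 0.25 * cos(3 * pi * x)
  )[seq_len(n_curves)]
  grid <- seq(0, 1, length.out = 1000L)
  n_int <- 0L
  for (i in seq_len(n_curves - 1L)) {
    for (j in seq((i + 1L), n_curves)) {
      dd <- funs[[i]](grid) - funs[[j]](grid)
      n_int <- n_int + sum(abs(diff(sign(dd))) > 0)
    }
  }
  stopifnot(n_int >= 2L)
  X <- NULL
  labels <- integer(0)
  for (i in seq_len(n_curves)) {
    x <- stats::runif(n_per_curve)
    P <- cbind(x, funs[[i]](x)) +
      matrix(stats::rnorm(2L * n_per_curve, sd = sigma), n_per_curve, 2L)
    X <- rbind(X, P)
    labels <- c(labels, rep(i, n_per_curve))
  }
  rownames(X) <- NULL
  list(X = pmin(pmax(X, 0), 1), labels = labels, curve_funs = funs,
       n_intersections = n_int)
}
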