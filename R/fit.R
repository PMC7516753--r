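#' Fitting parameters for a fixed graph structure
#'
#' @param trimming_radius trimming radius R0: data points farther than R0 from
#'   every node are invisible to the optimization for the current partition
#'   (they still contribute the constant R0^2 to the reported approximation
#'   error). `Inf` disables trimming.
#' @param max_iter maximum number of partition/solve iterations.
#' @param eps convergence tolerance: the fit stops when the maximum node
#'   displacement falls below `eps` times the diameter of the data bounding
#'   box.
#' @return a list of class `fit_params`.
#' @export
fit_params <- function(trimming_radius = Inf, max_iter = 200L, eps = 1e-3) {
  stopifnot(trimming_radius > 0, max_iter >= 1L, eps > 0)
  structure(list(trimming_radius = trimming_radius,
                 max_iter = as.integer(max_iter), eps = eps),
            class = "fit_params")
}

#' Partition data points by proximity to embedded graph nodes
#'
#' Assigns every data point to its nearest node in the Euclidean metric.
#' Ties are broken deterministically towards the lowest node index. Points
#' whose nearest-node distance exceeds the trimming radius are flagged as
#' trimmed and excluded from node loads during fitting.
#'
#' @param X numeric data matrix (points in rows).
#' @param positions node position matrix (nodes in rows, same number of
#'   columns as `X`).
#' @param trimming_radius trimming radius R0 (default `Inf`).
#' @return a list of class `graph_partition` with `assignment` (node index per
#'   point), `distance` (Euclidean distance to the assigned node), and
#'   `trimmed` (logical mask, `distance > R0`).
#' @export
partition_data <- function(X, positions, trimming_radius = Inf) {
  X <- as.matrix(X)
  positions <- as.matrix(positions)
  if (ncol(X) != ncol(positions))
    stop(sprintf("data has %d columns but node positions have %d",
                 ncol(X), ncol(positions)))
  d2 <- squared_distances(X, positions)
  assignment <- max.col(-d2, ties.method = "first")
  dist <- sqrt(pmax(d2[cbind(seq_len(nrow(X)), assignment)], 0))
  structure(list(assignment = assignment, distance = dist,
                 trimmed = dist > trimming_radius),
            class = "graph_partition")
}

squared_distances <- function(X, P) {
  # |x - p|^2 = |x|^2 - 2 x.p + |p|^2, guarded against negative round-off
  d2 <- outer(rowSums(X^2), rep(1, nrow(P))) - 2 * tcrossprod(X, P) +
    outer(rep(1, nrow(X)), rowSums(P^2))
  pmax(d2, 0)
}

#' Solve for the optimal embedding given a fixed partition
#'
#' Solves, per data-space coordinate, the linear system
#' \deqn{[\mathrm{diag}(n_j) + \tilde L]\,\phi = b,}
#' where \eqn{n_j} is the (normalized) weight load of node j over non-trimmed
#' points, \eqn{b_j} the normalized weighted sum of the points assigned to
#' node j, and \eqn{\tilde L} the summed elastic Laplacian. This is the exact
#' minimizer of the trimmed penalized error for the given partition. The
#' system matrix is symmetric positive (semi-)definite and sparse; a sparse
#' Cholesky factorization is used for a deterministic direct solve.
#'
#' @param X data matrix.
#' @param graph an `elastic_graph`.
#' @param partition a `graph_partition` of `X` onto the current embedding.
#' @param weights optional positive point weights (default all 1).
#' @return node position matrix (one row per node).
#' @export
solve_embedding <- function(X, graph, partition, weights = NULL) {
  X <- as.matrix(X)
  N <- nrow(X)
  if (is.null(weights)) weights <- rep(1, N)
  if (length(weights) != N || any(weights <= 0))
    stop("weights must be positive, one per data point")
  V <- graph$n_nodes
  sumw <- sum(weights)

  keep <- !partition$trimmed
  nj <- numeric(V)
  b <- matrix(0, V, ncol(X))
  if (any(keep)) {
    wk <- weights[keep]
    ak <- partition$assignment[keep]
    nj_tab <- rowsum(wk, group = ak)
    nj[as.integer(rownames(nj_tab))] <- nj_tab[, 1L] / sumw
    bk <- rowsum(X[keep, , drop = FALSE] * wk, group = ak)
    b[as.integer(rownames(bk)), ] <- bk / sumw
  }

  parts <- elastic_matrix_parts(graph)
  A <- Matrix::Matrix(parts$L_tilde + diag(nj, nrow = V), sparse = TRUE)
  A <- Matrix::forceSymmetric(A)
  phi <- tryCatch(
    suppressWarnings(as.matrix(Matrix::solve(A, b))),
    error = function(e) {
      stop(paste0(
        "singular embedding system: every connected component of the graph ",
        "needs at least one non-trimmed data point (", conditionMessage(e), ")"),
        call. = FALSE)
    })
  dimnames(phi) <- NULL
  phi
}

#' Fit a fixed elastic graph structure to data
#'
#' Alternates nearest-node partitioning of the data and the exact linear
#' solve for the node positions until the maximum node displacement falls
#' below the tolerance or the iteration budget is exhausted. This splitting
#' scheme decreases the objective
#' \deqn{U^\phi(X, G) = \frac{1}{\sum w_i}\sum_i w_i
#'  \min(\|X_i - \phi(V_{K(i)})\|^2, R_0^2) + U_E + U_R}
#' at every iteration.
#'
#' @param X data matrix (points in rows).
#' @param graph an `elastic_graph`.
#' @param positions initial node positions.
#' @param params a `fit_params` object.
#' @param weights optional positive point weights.
#' @param trace record the energy after every iteration (diagnostic).
#' @return a list of class `graph_fit` with `positions`, `energy` (see
#'   [energy_report()]), `partition`, `n_iter`, `converged`, and (if `trace`)
#'   `energy_trace`.
#' @export
fit_graph <- function(X, graph, positions, params = fit_params(),
                      weights = NULL, trace = FALSE) {
  X <- as.matrix(X)
  positions <- as_positions(positions, graph$n_nodes)
  if (ncol(positions) != ncol(X))
    stop("embedding dimension does not match the data")
  R0 <- params$trimming_radius
  scale <- data_diameter(X)
  if (scale == 0) scale <- 1

  energy_trace <- numeric(0)
  converged <- FALSE
  part <- partition_data(X, positions, R0)
  iter <- 0L
  for (iter in seq_len(params$max_iter)) {
    new_pos <- solve_embedding(X, graph, part, weights)
    delta <- max(sqrt(rowSums((new_pos - positions)^2)))
    positions <- new_pos
    part <- partition_data(X, positions, R0)
    if (trace) {
      energy_trace <- c(energy_trace,
                        energy_report(X, graph, positions, part,
                                      weights = weights,
                                      trimming_radius = R0)$U_total)
    }
    if (delta < params$eps * scale) {
      converged <- TRUE
      break
    }
  }

  out <- list(positions = positions,
              energy = energy_report(X, graph, positions, part,
                                     weights = weights, trimming_radius = R0),
              partition = part, n_iter = iter, converged = converged)
  if (trace) out$energy_trace <- energy_trace
  structure(out, class = "graph_fit")
}

data_diameter <- function(X) {
  rng <- apply(X, 2L, range)
  sqrt(sum((rng[2L, ] - rng[1L, ])^2))
}

#' Full energy report of an embedded graph against data
#'
#' Evaluates the trimmed, weighted approximation term
#' \eqn{\frac{1}{\sum w_i}\sum_i w_i \min(\|X_i-\phi(V_{K(i)})\|^2, R_0^2)}
#' plus the elastic energy terms \eqn{U_E} and \eqn{U_R}.
#'
#' @param X data matrix.
#' @param graph an `elastic_graph`.
#' @param positions node positions.
#' @param partition optional precomputed `graph_partition`; recomputed when
#'   missing.
#' @param weights optional positive point weights.
#' @param trimming_radius trimming radius R0.
#' @return a list of class `energy_report` with `U_total`,
#'   `approximation_term`, `U_E`, `U_R` and per-element diagnostics.
#' @export
energy_report <- function(X, graph, positions, partition = NULL,
                          weights = NULL, trimming_radius = Inf) {
  X <- as.matrix(X)
  if (is.null(weights)) weights <- rep(1, nrow(X))
  if (is.null(partition))
    partition <- partition_data(X, positions, trimming_radius)
  approx <- sum(weights * pmin(partition$distance^2, trimming_radius^2)) /
    sum(weights)
  el <- elastic_energy(graph, positions)
  structure(list(U_total = approx + el$U, approximation_term = approx,
                 U_E = el$U_E, U_R = el$U_R,
                 per_edge = el$per_edge, per_star = el$per_star,
                 n_trimmed = sum(partition$trimmed)),
            class = "energy_report")
}
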