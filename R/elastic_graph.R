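#' Construct an elastic graph
#'
#' An elastic graph is a simple undirected graph in which every edge carries a
#' stretching modulus \eqn{\lambda_i > 0} and every node of degree \eqn{\ge 2}
#' is the centre of a k-star (formed by all of its neighbours) carrying a
#' bending modulus \eqn{\mu_j \ge 0}. A global coefficient \eqn{\alpha \ge 0}
#' penalizes edges attached to high-degree branching points. Only primitive
#' elastic graphs are supported: the star selection is fully determined by the
#' graph structure, and leaves always carry \eqn{\mu = 0}.
#'
#' @param edges two-column integer matrix of undirected edges (1-based node
#'   indices); may have zero rows for an edgeless graph.
#' @param n_nodes number of nodes; defaults to the largest index in `edges`.
#' @param lambda stretching modulus, a scalar recycled over edges or a
#'   per-edge vector. Must be strictly positive. Default 0.01.
#' @param mu bending modulus, a scalar assigned to every star centre (nodes of
#'   degree >= 2) or a per-node vector. Leaves must carry 0. Default 0.1.
#' @param alpha branching penalty coefficient, dimensionless, >= 0. Each edge
#'   contributes with effective modulus
#'   \eqn{\lambda_i + \alpha(\max(2, \deg_0, \deg_1) - 2)}. Default 0.
#' @return an object of class `elastic_graph`.
#' @examples
#' g <- elastic_graph(rbind(c(1, 2), c(2, 3)), lambda = 0.01, mu = 0.1)
#' node_degrees(g)
#' @export
elastic_graph <- function(edges, n_nodes = NULL, lambda = 0.01, mu = 0.1,
                          alpha = 0) {
  edges <- as_edge_matrix(edges)
  if (is.null(n_nodes)) {
    n_nodes <- if (nrow(edges) == 0L) 0L else max(edges)
  }
  n_nodes <- as.integer(n_nodes)
  if (n_nodes < 1L) stop("an elastic graph needs at least one node")
  n_edges <- nrow(edges)

  lambdas <- rep_len(as.numeric(lambda), n_edges)
  deg <- tabulate(edges, nbins = n_nodes)
  if (length(mu) == 1L) {
    mus <- ifelse(deg >= 2L, as.numeric(mu), 0)
  } else {
    if (length(mu) != n_nodes)
      stop("`mu` must be a scalar or one value per node")
    mus <- as.numeric(mu)
  }
  g <- structure(
    list(n_nodes = n_nodes, edges = edges, lambdas = lambdas, mus = mus,
         alpha = as.numeric(alpha)),
    class = "elastic_graph"
  )
  validate_elastic_graph(g)
  g
}

as_edge_matrix <- function(edges) {
  if (is.null(edges) || length(edges) == 0L) {
    return(matrix(integer(0), ncol = 2L))
  }
  edges <- matrix(as.integer(edges), ncol = 2L)
  # canonical form: small index first, rows ordered
  flip <- edges[, 1L] > edges[, 2L]
  edges[flip, ] <- edges[flip, c(2L, 1L), drop = FALSE]
  edges[order(edges[, 1L], edges[, 2L]), , drop = FALSE]
}

validate_elastic_graph <- function(g) {
  e <- g$edges
  if (nrow(e) > 0L) {
    if (any(e < 1L) || any(e > g$n_nodes))
      stop("edge indices out of range")
    if (any(e[, 1L] == e[, 2L]))
      stop("self-loops are not allowed in an elastic graph")
    key <- paste(e[, 1L], e[, 2L])
    if (anyDuplicated(key))
      stop("duplicate edges are not allowed in an elastic graph")
  }
  if (length(g$lambdas) != nrow(e) || any(g$lambdas < 0))
    stop("edge stretching moduli lambda must not be negative")
  if (length(g$mus) != g$n_nodes || any(g$mus < 0))
    stop("star bending moduli mu must be non-negative")
  deg <- node_degrees(g)
  if (any(g$mus[deg < 2L] != 0))
    stop("nodes of degree < 2 are not star centres and must have mu = 0")
  if (g$alpha < 0) stop("alpha must be non-negative")
  invisible(g)
}

#' Node degrees of an elastic graph
#' @param graph an `elastic_graph`.
#' @return integer vector of degrees.
#' @export
node_degrees <- function(graph) {
  tabulate(graph$edges, nbins = graph$n_nodes)
}

#' @export
print.elastic_graph <- function(x, ...) {
  deg <- node_degrees(x)
  cat(sprintf("Elastic graph: %d nodes, %d edges, %d star centre(s)\n",
              x$n_nodes, nrow(x$edges), sum(deg >= 2L)))
  if (nrow(x$edges) > 0L)
    cat(sprintf("  lambda in [%g, %g], mu max %g, alpha = %g\n",
                min(x$lambdas), max(x$lambdas), max(x$mus), x$alpha))
  invisible(x)
}

adjacency_list <- function(graph) {
  adj <- vector("list", graph$n_nodes)
  for (i in seq_len(graph$n_nodes)) adj[[i]] <- integer(0)
  e <- graph$edges
  for (r in seq_len(nrow(e))) {
    adj[[e[r, 1L]]] <- c(adj[[e[r, 1L]]], e[r, 2L])
    adj[[e[r, 2L]]] <- c(adj[[e[r, 2L]]], e[r, 1L])
  }
  lapply(adj, sort)
}

#' Effective per-edge moduli including the branching penalty
#'
#' Each edge contributes to the stretching energy with the coefficient
#' \eqn{\lambda_i + \alpha(\max(2, \deg(E^{(i)}(0)), \deg(E^{(i)}(1))) - 2)},
#' so edges attached to stars of order k > 2 pay a surcharge proportional to
#' k - 2.
#'
#' @param graph an `elastic_graph`.
#' @return numeric vector, one value per edge.
#' @export
effective_lambdas <- function(graph) {
  e <- graph$edges
  if (nrow(e) == 0L) return(numeric(0))
  deg <- node_degrees(graph)
  graph$lambdas +
    graph$alpha * (pmax(2L, deg[e[, 1L]], deg[e[, 2L]]) - 2L)
}

weighted_laplacian <- function(A) {
  diag(colSums(A), nrow = nrow(A)) - A
}

#' Elastic matrix decomposition of a graph
#'
#' Builds the elastic matrix EM = Lambda + M and its auxiliary decomposition:
#' `Lambda` is the weighted adjacency matrix of (effective) edge moduli, `M`
#' the diagonal matrix of star moduli, `Lambda_star_edges` the adjacency of
#' the positive springs connecting star centres to their neighbours (weights
#' \eqn{\mu_j/k_j}), and `Lambda_star_leafs` the adjacency of the negative
#' (repulsive) springs between pairs of non-central star nodes (weights
#' \eqn{-\mu_j/k_j^2}). `L_tilde` is the summed Laplacian
#' \eqn{\tilde L = L(\Lambda) + L(\Lambda_{se}) + L(\Lambda_{sl})}, which is
#' positive semi-definite by construction and encodes the full elastic
#' quadratic form: summed per coordinate,
#' \eqn{\phi^\top \tilde L \phi = U_E + U_R}.
#'
#' @param graph an `elastic_graph`.
#' @param effective use the alpha-corrected edge moduli in Lambda (default);
#'   set `FALSE` for the raw lambda values.
#' @return a list of class `elastic_matrix_parts` with components `EM`,
#'   `Lambda`, `M`, `Lambda_star_edges`, `Lambda_star_leafs`, `L_tilde`, and
#'   `degrees`.
#' @export
elastic_matrix_parts <- function(graph, effective = TRUE) {
  validate_elastic_graph(graph)
  V <- graph$n_nodes
  e <- graph$edges
  deg <- node_degrees(graph)

  Lam <- matrix(0, V, V)
  if (nrow(e) > 0L) {
    le <- if (effective) effective_lambdas(graph) else graph$lambdas
    Lam[cbind(e[, 1L], e[, 2L])] <- le
    Lam[cbind(e[, 2L], e[, 1L])] <- le
  }
  M <- diag(graph$mus, nrow = V)

  Lse <- matrix(0, V, V)
  Lsl <- matrix(0, V, V)
  adj <- adjacency_list(graph)
  for (j in which(deg >= 2L)) {
    nb <- adj[[j]]
    k <- deg[j]
    muk <- graph$mus[j] / k
    Lse[j, nb] <- Lse[j, nb] + muk
    Lse[nb, j] <- Lse[nb, j] + muk
    if (k >= 2L) {
      pr <- utils::combn(nb, 2L)
      w <- graph$mus[j] / k^2
      for (c in seq_len(ncol(pr))) {
        p <- pr[1L, c]; q <- pr[2L, c]
        Lsl[p, q] <- Lsl[p, q] - w
        Lsl[q, p] <- Lsl[q, p] - w
      }
    }
  }

  structure(
    list(EM = Lam + M, Lambda = Lam, M = M,
         Lambda_star_edges = Lse, Lambda_star_leafs = Lsl,
         L_tilde = weighted_laplacian(Lam) + weighted_laplacian(Lse) +
           weighted_laplacian(Lsl),
         degrees = deg),
    class = "elastic_matrix_parts"
  )
}

#' Elastic energy of a graph embedding
#'
#' Computes the stretching term
#' \eqn{U_E = \sum_i [\lambda_i + \alpha(\max(2,\deg_0,\deg_1)-2)]
#' \|\phi(E^{(i)}(0)) - \phi(E^{(i)}(1))\|^2} and the harmonicity
#' (bending) term
#' \eqn{U_R = \sum_j \mu_j \|\phi(S^{(j)}(0)) - \frac{1}{k_j}\sum_i
#' \phi(S^{(j)}(i))\|^2} of an embedded elastic graph. \eqn{U_R} vanishes for
#' harmonic embeddings, in which every star centre sits at the mean of its
#' neighbours.
#'
#' @param graph an `elastic_graph`.
#' @param positions numeric matrix, one row per node.
#' @return a list with `U_E`, `U_R`, `U` (their sum), and the per-edge /
#'   per-star contributions.
#' @export
elastic_energy <- function(graph, positions) {
  positions <- as_positions(positions, graph$n_nodes)
  e <- graph$edges
  deg <- node_degrees(graph)

  per_edge <- numeric(nrow(e))
  if (nrow(e) > 0L) {
    d <- positions[e[, 1L], , drop = FALSE] - positions[e[, 2L], , drop = FALSE]
    per_edge <- effective_lambdas(graph) * rowSums(d * d)
  }

  centers <- which(deg >= 2L)
  per_star <- numeric(length(centers))
  if (length(centers) > 0L) {
    adj <- adjacency_list(graph)
    for (i in seq_along(centers)) {
      j <- centers[i]
      nb_mean <- colMeans(positions[adj[[j]], , drop = FALSE])
      dev <- positions[j, ] - nb_mean
      per_star[i] <- graph$mus[j] * sum(dev * dev)
    }
  }
  names(per_star) <- centers

  U_E <- sum(per_edge)
  U_R <- sum(per_star)
  list(U_E = U_E, U_R = U_R, U = U_E + U_R,
       per_edge = per_edge, per_star = per_star)
}

as_positions <- function(positions, n_nodes) {
  positions <- as.matrix(positions)
  if (!is.numeric(positions) || anyNA(positions) || any(!is.finite(positions)))
    stop("node positions must be finite numeric values")
  if (nrow(positions) != n_nodes)
    stop(sprintf("embedding has %d rows but the graph has %d nodes",
                 nrow(positions), n_nodes))
  positions
}

edge_lengths <- function(graph, positions) {
  e <- graph$edges
  if (nrow(e) == 0L) return(numeric(0))
  d <- positions[e[, 1L], , drop = FALSE] - positions[e[, 2L], , drop = FALSE]
  sqrt(rowSums(d * d))
}
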