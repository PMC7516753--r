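# Shared fixtures and independent oracles for the test suite.

# random labelled tree on n nodes: node i attaches to a random earlier node
random_tree_edges <- function(n) {
  if (n < 2L) return(NULL)
  cbind(vapply(2:n, function(i) sample.int(i - 1L, 1L), integer(1L)), 2:n)
}

random_elastic_tree <- function(n, alpha = 0) {
  edges <- random_tree_edges(n)
  g0 <- elastic_graph(edges, n_nodes = n, lambda = 1, mu = 1, alpha = alpha)
  deg <- node_degrees(g0)
  mus <- ifelse(deg >= 2L, runif(n, 0.05, 0.5), 0)
  elastic_graph(edges, n_nodes = n, lambda = runif(nrow(edges), 0.01, 1),
                mu = mus, alpha = alpha)
}

random_positions <- function(n, m) matrix(rnorm(n * m), n, m)

# direct loop evaluation of the stretching energy (independent of the
# vectorized implementation)
oracle_U_E <- function(graph, pos) {
  deg <- node_degrees(graph)
  tot <- 0
  for (r in seq_len(nrow(graph$edges))) {
    a <- graph$edges[r, 1L]; b <- graph$edges[r, 2L]
    coef <- graph$lambdas[r] +
      graph$alpha * (max(2, deg[a], deg[b]) - 2)
    tot <- tot + coef * sum((pos[a, ] - pos[b, ])^2)
  }
  tot
}

# direct evaluation of the harmonicity term: mu_j * |center - mean(leaves)|^2
oracle_U_R <- function(graph, pos) {
  deg <- node_degrees(graph)
  adj <- epgraph:::adjacency_list(graph)
  tot <- 0
  for (j in which(deg >= 2L)) {
    m <- colMeans(pos[adj[[j]], , drop = FALSE])
    tot <- tot + graph$mus[j] * sum((pos[j, ] - m)^2)
  }
  tot
}

# spring decomposition of the harmonicity term: positive springs centre-leaf
# with moduli mu/k minus repulsive springs between leaf pairs with mu/k^2
oracle_U_R_springs <- function(graph, pos) {
  deg <- node_degrees(graph)
  adj <- epgraph:::adjacency_list(graph)
  tot <- 0
  for (j in which(deg >= 2L)) {
    nb <- adj[[j]]
    k <- deg[j]
    pl <- sum(vapply(nb, function(i) sum((pos[j, ] - pos[i, ])^2),
                     numeric(1L))) * graph$mus[j] / k
    mn <- 0
    if (k >= 2L) {
      pr <- utils::combn(nb, 2L)
      for (c in seq_len(ncol(pr)))
        mn <- mn + sum((pos[pr[1L, c], ] - pos[pr[2L, c], ])^2)
    }
    tot <- tot + pl - graph$mus[j] / k^2 * mn
  }
  tot
}

# full objective of the trimmed fit, evaluated directly from its definition
oracle_total_energy <- function(X, graph, pos, R0 = Inf, weights = NULL) {
  if (is.null(weights)) weights <- rep(1, nrow(X))
  d2 <- epgraph:::squared_distances(as.matrix(X), pos)
  dmin2 <- apply(d2, 1L, min)
  sum(weights * pmin(dmin2, R0^2)) / sum(weights) +
    oracle_U_E(graph, pos) + oracle_U_R(graph, pos)
}

# numeric minimization of the objective at a FIXED partition (quadratic in
# the positions), used as an oracle for the linear-solve step
oracle_minimize_at_partition <- function(X, graph, part, start,
                                         weights = NULL) {
  X <- as.matrix(X)
  if (is.null(weights)) weights <- rep(1, nrow(X))
  m <- ncol(X)
  obj <- function(par) {
    pos <- matrix(par, graph$n_nodes, m)
    keep <- !part$trimmed
    approx <- sum(weights[keep] *
                    rowSums((X[keep, , drop = FALSE] -
                             pos[part$assignment[keep], , drop = FALSE])^2)) /
      sum(weights)
    approx + oracle_U_E(graph, pos) + oracle_U_R(graph, pos)
  }
  fit <- optim(as.numeric(start), obj, method = "BFGS",
               control = list(maxit = 2000, reltol = 1e-14))
  list(positions = matrix(fit$par, graph$n_nodes, m), value = fit$value)
}

# minimal principal_graph-shaped object for downstream helpers
manual_result <- function(edges, positions, lambda = 0.01, mu = 0.1,
                          alpha = 0, mode = "custom") {
  g <- elastic_graph(edges, n_nodes = nrow(positions), lambda = lambda,
                     mu = mu, alpha = alpha)
  structure(list(graph = g, positions = positions, energy = NULL,
                 partition = NULL, history = data.frame(),
                 config = list(mode = mode, mu = mu), trimming_radius = Inf),
            class = "principal_graph")
}

path_edges <- function(n) cbind(seq_len(n - 1L), 2:n)
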