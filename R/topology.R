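#' Configuration for principal graph learning
#'
#' @param mode target topology class. `"curve"` grows a path by edge
#'   bisection, `"circle"` grows a closed curve from a 4-node ring, `"tree"`
#'   alternates two growing steps (`bisect_edge`, `add_node_to_node`) with one
#'   shrinking step (`remove_leaf`, `shrink_internal_edge`), adding one node
#'   net per cycle. `"custom"` uses `grammar_schedule` as given.
#' @param n_nodes target number of nodes; default `ceiling(sqrt(N))` (capped
#'   at 100) chosen at fit time.
#' @param lambda,mu,alpha elasticity moduli; see [elastic_graph()]. By default
#'   lambda = 0.01 with mu one order of magnitude larger, and no branching
#'   penalty (alpha = 0). Set alpha to about 0.01 to discourage high-order
#'   stars, or about 1 to forbid branching altogether.
#' @param trimming_radius trimming radius R0, or `"auto"` for the median of
#'   pairwise point distances on a subsample (see [suggest_trimming_radius()]),
#'   or `Inf` (default) for no trimming.
#' @param eps,max_iter convergence control for the final fits (see
#'   [fit_params()]).
#' @param candidate_iter iteration budget used when scoring grammar
#'   candidates (warm-started from the grammar-updated embedding); the winner
#'   of every step is then refitted with the full `max_iter` budget.
#' @param max_candidates per-operation candidate budget k for the reduced
#'   search; `Inf` (default) tests every admissible element.
#' @param init initialization: `"pc1"` (two nodes along the first principal
#'   component), `"density"` (two neighbouring points in the densest region;
#'   recommended with finite R0), `"mst"` (minimum spanning tree over k-means
#'   centroids), or a list with elements `graph` and `positions`.
#' @param n_centroids number of centroids for `init = "mst"`.
#' @param seed optional integer seed making the whole run reproducible.
#' @param grammar_schedule list of character vectors (one grammar set per
#'   step, cycled); only used for `mode = "custom"`.
#' @return a list of class `learn_config`.
#' @export
learn_config <- function(mode = c("tree", "curve", "circle", "custom"),
                         n_nodes = NULL, lambda = 0.01, mu = 0.1, alpha = 0,
                         trimming_radius = Inf, eps = 1e-3, max_iter = 200L,
                         candidate_iter = 10L, max_candidates = Inf,
                         init = "pc1", n_centroids = 10L, seed = NULL,
                         grammar_schedule = NULL) {
  mode <- match.arg(mode)
  if (mode == "custom" && is.null(grammar_schedule))
    stop("mode = 'custom' requires a grammar_schedule")
  structure(list(mode = mode, n_nodes = n_nodes, lambda = lambda, mu = mu,
                 alpha = alpha, trimming_radius = trimming_radius, eps = eps,
                 max_iter = as.integer(max_iter),
                 candidate_iter = as.integer(candidate_iter),
                 max_candidates = max_candidates, init = init,
                 n_centroids = as.integer(n_centroids), seed = seed,
                 grammar_schedule = grammar_schedule),
            class = "learn_config")
}

grammar_schedule_for <- function(config) {
  switch(config$mode,
         curve = list("bisect_edge"),
         circle = list("bisect_edge"),
         tree = list(c("bisect_edge", "add_node_to_node"),
                     c("bisect_edge", "add_node_to_node"),
                     c("remove_leaf", "shrink_internal_edge")),
         custom = config$grammar_schedule)
}

#' Two-node initialization along the first principal component
#'
#' Places a single edge centred at the data mean and oriented along the first
#' principal component, with half-length equal to the standard deviation of
#' the projections.
#'
#' @param X data matrix (N >= 2 rows).
#' @param lambda,mu,alpha moduli for the initial graph.
#' @return list with `graph` (an `elastic_graph`) and `positions`.
#' @export
initialize_pc1 <- function(X, lambda = 0.01, mu = 0.1, alpha = 0) {
  X <- as.matrix(X)
  if (nrow(X) < 2L) stop("need at least two data points")
  ctr <- colMeans(X)
  Xc <- sweep(X, 2L, ctr)
  sv <- svd(Xc, nu = 0L, nv = 1L)
  v <- sv$v[, 1L]
  s <- stats::sd(Xc %*% v)
  if (s == 0) s <- 1e-8
  list(graph = elastic_graph(rbind(c(1L, 2L)), n_nodes = 2L, lambda = lambda,
                             mu = mu, alpha = alpha),
       positions = rbind(ctr - s * v, ctr + s * v))
}

#' Density-based two-node initialization for robust (trimmed) fitting
#'
#' Puts the first node on the data point with the highest local density
#' (the largest number of neighbours within `radius`, estimated on a random
#' subsample of at most `n_sub` points) and the second node on the nearest
#' distinct data point. With a finite trimming radius the graph then grows
#' outwards from the densest region, "crawling" along the data.
#'
#' @param X data matrix.
#' @param radius neighbourhood radius used for the density estimate
#'   (typically the trimming radius R0).
#' @param n_sub maximum subsample size for density counting.
#' @param lambda,mu,alpha moduli for the initial graph.
#' @return list with `graph` and `positions`.
#' @export
initialize_density <- function(X, radius, n_sub = 1000L, lambda = 0.01,
                               mu = 0.1, alpha = 0) {
  X <- as.matrix(X)
  N <- nrow(X)
  if (N < 2L) stop("need at least two data points")
  sub <- if (N > n_sub) sort(sample.int(N, n_sub)) else seq_len(N)
  d2 <- squared_distances(X[sub, , drop = FALSE], X[sub, , drop = FALSE])
  counts <- rowSums(d2 <= radius^2) # includes self; constant offset
  first <- sub[which.max(counts)]
  d2all <- squared_distances(X[first, , drop = FALSE], X)[1L, ]
  d2all[first] <- Inf
  d2all[d2all == 0] <- Inf # must not coincide
  if (all(!is.finite(d2all)))
    stop("no data point distinct from the densest point")
  second <- which.min(d2all)
  list(graph = elastic_graph(rbind(c(1L, 2L)), n_nodes = 2L, lambda = lambda,
                             mu = mu, alpha = alpha),
       positions = rbind(X[first, ], X[second, ]))
}

#' Minimum-spanning-tree initialization over k-means centroids
#'
#' Pre-clusters the data with k-means and connects the centroids by their
#' Euclidean minimum spanning tree, giving a tree-shaped starting structure.
#'
#' @param X data matrix.
#' @param n_centroids number of k-means centroids.
#' @param lambda,mu,alpha moduli for the initial graph.
#' @return list with `graph` and `positions`.
#' @export
initialize_mst <- function(X, n_centroids = 10L, lambda = 0.01, mu = 0.1,
                           alpha = 0) {
  X <- as.matrix(X)
  n_unique <- nrow(unique(X))
  if (n_unique < 2L) {
    warning("degenerate data (all points identical): single-node start")
    return(list(graph = elastic_graph(NULL, n_nodes = 1L, lambda = lambda,
                                      mu = mu, alpha = alpha),
                positions = X[1L, , drop = FALSE]))
  }
  k <- min(n_centroids, n_unique)
  km <- stats::kmeans(X, centers = k, nstart = 5L, iter.max = 50L)
  ctr <- km$centers
  g_full <- igraph::graph_from_adjacency_matrix(
    as.matrix(stats::dist(ctr)), mode = "undirected", weighted = TRUE)
  mst <- igraph::mst(g_full)
  edges <- igraph::as_edgelist(mst, names = FALSE)
  storage.mode(edges) <- "integer"
  list(graph = elastic_graph(edges, n_nodes = k, lambda = lambda, mu = mu,
                             alpha = alpha),
       positions = unname(ctr))
}

ring_init <- function(X, lambda, mu, alpha) {
  X <- as.matrix(X)
  ctr <- colMeans(X)
  Xc <- sweep(X, 2L, ctr)
  sv <- svd(Xc, nu = 0L, nv = 2L)
  v1 <- sv$v[, 1L]
  v2 <- if (ncol(sv$v) >= 2L) sv$v[, 2L] else v1
  s1 <- stats::sd(Xc %*% v1); s2 <- stats::sd(Xc %*% v2)
  if (s1 == 0) s1 <- 1e-8
  if (s2 == 0) s2 <- s1
  theta <- pi / 2 * (0:3)
  pos <- t(vapply(theta, function(a) ctr + cos(a) * s1 * v1 + sin(a) * s2 * v2,
                  numeric(ncol(X))))
  list(graph = elastic_graph(rbind(c(1L, 2L), c(2L, 3L), c(3L, 4L), c(4L, 1L)),
                             n_nodes = 4L, lambda = lambda, mu = mu,
                             alpha = alpha),
       positions = pos)
}

#' Suggest a trimming radius from the pairwise distance distribution
#'
#' Returns the median of the pairwise Euclidean distances computed on a
#' random subsample, a standard initial guess for the trimming radius R0.
#'
#' @param X data matrix.
#' @param n_sub maximum subsample size.
#' @return a positive scalar.
#' @export
suggest_trimming_radius <- function(X, n_sub = 500L) {
  X <- as.matrix(X)
  sub <- if (nrow(X) > n_sub) sort(sample.int(nrow(X), n_sub)) else
    seq_len(nrow(X))
  stats::median(stats::dist(X[sub, , drop = FALSE]))
}

#' Learn an elastic principal graph
#'
#' Structure learning by energy-minimizing grammar application: starting from
#' a small initial graph, each step applies every operation of the current
#' grammar set to every admissible element, re-optimizes each candidate with
#' [fit_graph()] (a short warm-started fit), and keeps the candidate with the
#' lowest total energy; the winner is then fully refitted. Steps repeat,
#' cycling through the grammar schedule, until the graph reaches the target
#' number of nodes.
#'
#' @param X data matrix (points in rows) or `Dataset`-like data frame.
#' @param config a [learn_config()] object.
#' @param weights optional positive point weights.
#' @return an object of class `principal_graph`: a list with `graph`,
#'   `positions`, `energy`, `partition`, `history` (one row per accepted
#'   step), and `config`.
#' @examples
#' set.seed(1)
#' X <- cbind(seq(0, 1, length.out = 60), rnorm(60, sd = 0.03))
#' pg <- learn_graph(X, learn_config(mode = "curve", n_nodes = 8))
#' table(node_degrees(pg$graph))
#' @export
learn_graph <- function(X, config = learn_config(), weights = NULL) {
  X <- as.matrix(X)
  if (!is.null(config$seed)) set.seed(config$seed)
  n_target <- config$n_nodes
  if (is.null(n_target)) n_target <- min(100L, ceiling(sqrt(nrow(X))))
  R0 <- config$trimming_radius
  if (identical(R0, "auto")) R0 <- suggest_trimming_radius(X)

  init <- if (is.list(config$init)) {
    list(graph = config$init$graph, positions = config$init$positions)
  } else if (config$mode == "circle") {
    ring_init(X, config$lambda, config$mu, config$alpha)
  } else {
    switch(config$init,
           pc1 = initialize_pc1(X, config$lambda, config$mu, config$alpha),
           density = initialize_density(X, radius = if (is.finite(R0)) R0 else
             suggest_trimming_radius(X), lambda = config$lambda,
             mu = config$mu, alpha = config$alpha),
           mst = initialize_mst(X, config$n_centroids, config$lambda,
                                config$mu, config$alpha),
           stop("unknown init: ", config$init))
  }
  if (n_target < init$graph$n_nodes)
    stop("n_nodes must be at least the initial node count")

  fp_full <- fit_params(trimming_radius = R0, max_iter = config$max_iter,
                        eps = config$eps)
  fp_cand <- fit_params(trimming_radius = R0,
                        max_iter = config$candidate_iter, eps = config$eps)

  fit <- fit_graph(X, init$graph, init$positions, fp_full, weights)
  graph <- init$graph
  positions <- fit$positions

  schedule <- grammar_schedule_for(config)
  history <- list()
  step <- 0L
  idle_steps <- 0L
  max_steps <- 12L * n_target + 10L

  while (graph$n_nodes < n_target && step < max_steps) {
    gset <- schedule[[step %% length(schedule) + 1L]]
    step <- step + 1L
    cands <- generate_candidates(graph, positions, gset, X = X,
                                 partition = fit$partition,
                                 max_candidates = config$max_candidates,
                                 default_mu = config$mu)
    if (length(cands) == 0L) {
      idle_steps <- idle_steps + 1L
      if (idle_steps >= length(schedule)) break
      next
    }
    idle_steps <- 0L
    energies <- numeric(length(cands))
    fits <- vector("list", length(cands))
    for (i in seq_along(cands)) {
      fits[[i]] <- fit_graph(X, cands[[i]]$graph, cands[[i]]$positions,
                             fp_cand, weights)
      energies[i] <- fits[[i]]$energy$U_total
    }
    best <- which.min(energies) # ties resolve to the first candidate
    graph <- cands[[best]]$graph
    fit <- fit_graph(X, graph, fits[[best]]$positions, fp_full, weights)
    positions <- fit$positions
    history[[length(history) + 1L]] <-
      data.frame(step = step, op = cands[[best]]$op_label,
                 n_nodes = graph$n_nodes, n_edges = nrow(graph$edges),
                 energy = fit$energy$U_total,
                 n_candidates = length(cands))
  }

  structure(list(graph = graph, positions = positions, energy = fit$energy,
                 partition = fit$partition,
                 history = if (length(history)) do.call(rbind, history) else
                   data.frame(),
                 config = config, trimming_radius = R0),
            class = "principal_graph")
}

#' @export
print.principal_graph <- function(x, ...) {
  deg <- node_degrees(x$graph)
  cat(sprintf(
    "Principal graph (%s): %d nodes, %d edges, %d branching point(s)\n",
    x$config$mode, x$graph$n_nodes, nrow(x$graph$edges), sum(deg >= 3L)))
  cat(sprintf("  energy U = %.6g (approx %.6g, U_E %.6g, U_R %.6g)\n",
              x$energy$U_total, x$energy$approximation_term, x$energy$U_E,
              x$energy$U_R))
  invisible(x)
}

#' Extend leaf nodes to cover extreme data points
#'
#' Graph nodes sit at local data means, so the leaves of a fitted graph stop
#' short of the extreme points of the distribution. This fine-tuning step
#' moves each leaf (or appends one node per leaf) outwards along its terminal
#' edge direction so that the most extreme projections of the points assigned
#' to the leaf fall within the terminal edge.
#'
#' @param result a `principal_graph`.
#' @param X data matrix.
#' @param mode `"move"` relocates each leaf; `"append"` adds one new node per
#'   leaf (keeping the original leaf position as an internal node).
#' @param factor fraction of the extreme excess projection to cover
#'   (0 = no change, 1 = cover the most extreme point).
#' @return an updated `principal_graph` (topology unchanged for `"move"`).
#' @export
extend_leaves <- function(result, X, mode = c("move", "append"), factor = 1) {
  mode <- match.arg(mode)
  X <- as.matrix(X)
  graph <- result$graph
  positions <- result$positions
  deg <- node_degrees(graph)
  leaves <- which(deg == 1L)
  if (length(leaves) == 0L) {
    warning("graph has no leaves; nothing to extend")
    return(result)
  }
  if (factor == 0) return(result)
  part <- partition_data(X, positions, result$trimming_radius %||% Inf)
  adj <- adjacency_list(graph)
  for (leaf in leaves) {
    nb <- adj[[leaf]]
    u <- positions[leaf, ] - positions[nb, ]
    len <- sqrt(sum(u^2))
    if (len == 0) next
    u <- u / len
    pts <- which(part$assignment == leaf & !part$trimmed)
    if (length(pts) == 0L) next
    proj <- as.numeric(
      (X[pts, , drop = FALSE] -
         matrix(positions[leaf, ], length(pts), ncol(X), byrow = TRUE)) %*% u)
    excess <- max(proj)
    if (excess <= 0) next
    target <- positions[leaf, ] + factor * excess * u
    if (mode == "move") {
      positions[leaf, ] <- target
    } else {
      cand <- add_node_to_node(graph, positions, leaf,
                               default_mu = result$config$mu %||% 0.1)
      graph <- cand$graph
      positions <- cand$positions
      positions[nrow(positions), ] <- target
    }
  }
  refresh_result(result, graph, positions, X)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

refresh_result <- function(result, graph, positions, X) {
  R0 <- result$trimming_radius %||% Inf
  part <- partition_data(X, positions, R0)
  result$graph <- graph
  result$positions <- positions
  result$partition <- part
  result$energy <- energy_report(X, graph, positions, part,
                                 trimming_radius = R0)
  result
}

#' Prune weakly supported edges
#'
#' Removes edges onto which fewer than `min_points` data points project,
#' drops nodes left isolated, and re-optimizes the remaining embedding with
#' [fit_graph()].
#'
#' @param result a `principal_graph`.
#' @param X data matrix.
#' @param min_points minimum number of projected points for an edge to
#'   survive; 0 returns the input unchanged.
#' @return an updated `principal_graph`.
#' @export
prune_edges <- function(result, X, min_points) {
  if (min_points <= 0L) return(result)
  X <- as.matrix(X)
  graph <- result$graph
  proj <- project_points(X, result)
  counts <- tabulate(proj$edge, nbins = nrow(graph$edges))
  drop <- which(counts < min_points)
  if (length(drop) == 0L) return(result)
  edges <- graph$edges[-drop, , drop = FALSE]
  lambdas <- graph$lambdas[-drop]
  keep_nodes <- sort(unique(as.integer(edges)))
  if (length(keep_nodes) == 0L)
    stop("pruning removed every edge; lower min_points")
  remap <- integer(graph$n_nodes)
  remap[keep_nodes] <- seq_along(keep_nodes)
  edges[] <- remap[edges]
  mus <- graph$mus[keep_nodes]
  new_deg <- tabulate(edges, nbins = length(keep_nodes))
  mus[new_deg < 2L] <- 0
  g <- elastic_graph(edges, n_nodes = length(keep_nodes), lambda = lambdas,
                     mu = mus, alpha = graph$alpha)
  fp <- fit_params(trimming_radius = result$trimming_radius %||% Inf,
                   max_iter = result$config$max_iter %||% 200L,
                   eps = result$config$eps %||% 1e-3)
  fit <- fit_graph(X, g, result$positions[keep_nodes, , drop = FALSE], fp)
  refresh_result(result, g, fit$positions, X)
}

#' Approximate a dataset by a principal forest
#'
#' With a finite trimming radius, a principal graph only covers the part of
#' the data reachable from its initialization. This helper repeatedly runs
#' [learn_graph()] with density-based initialization, removing the points
#' approximated within R0 after each round, until a target coverage is
#' reached, yielding a set of disconnected components (a principal forest).
#'
#' @param X data matrix.
#' @param config a `learn_config` with finite `trimming_radius`.
#' @param max_components maximum number of components to fit.
#' @param coverage stop once this fraction of points lies within R0 of some
#'   component.
#' @return list of `principal_graph` objects, with attribute `covered`
#'   (logical per point).
#' @export
learn_forest <- function(X, config, max_components = 5L, coverage = 0.99) {
  X <- as.matrix(X)
  R0 <- config$trimming_radius
  if (identical(R0, "auto")) R0 <- suggest_trimming_radius(X)
  if (!is.finite(R0)) stop("learn_forest requires a finite trimming radius")
  config$trimming_radius <- R0
  config$init <- "density"
  remaining <- rep(TRUE, nrow(X))
  covered <- rep(FALSE, nrow(X))
  forest <- list()
  for (comp in seq_len(max_components)) {
    if (sum(remaining) < 2L) break
    pg <- learn_graph(X[remaining, , drop = FALSE], config)
    forest[[comp]] <- pg
    d <- partition_data(X, pg$positions, Inf)$distance
    covered <- covered | d <= R0
    remaining <- !covered
    if (mean(covered) >= coverage) break
  }
  attr(forest, "covered") <- covered
  forest
}
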