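#' Project data points onto the edges of a fitted graph
#'
#' Each point is orthogonally projected onto every edge segment (with the
#' projection parameter clamped to \[0, 1\]) and assigned to the edge with
#' the smallest residual; ties resolve to the lowest edge index. For an
#' edgeless single-node graph, points project onto the node.
#'
#' @param X data matrix.
#' @param result a `principal_graph`, or any list with `graph` and
#'   `positions`.
#' @return a list of class `graph_projection` with `edge` (edge index per
#'   point), `t` (position along the edge in \[0, 1\]), `coords` (projected
#'   coordinates) and `residual` (squared distance to the projection).
#' @export
project_points <- function(X, result) {
  X <- as.matrix(X)
  graph <- result$graph
  pos <- result$positions
  N <- nrow(X)
  E <- nrow(graph$edges)
  if (E == 0L) {
    d2 <- squared_distances(X, pos)
    return(structure(list(edge = rep(NA_integer_, N), t = rep(0, N),
                          coords = pos[rep(1L, N), , drop = FALSE],
                          residual = d2[, 1L]),
                     class = "graph_projection"))
  }
  best_res <- rep(Inf, N)
  best_edge <- integer(N)
  best_t <- numeric(N)
  best_xy <- matrix(0, N, ncol(X))
  for (e in seq_len(E)) {
    a <- pos[graph$edges[e, 1L], ]
    b <- pos[graph$edges[e, 2L], ]
    ab <- b - a
    len2 <- sum(ab^2)
    t <- if (len2 == 0) rep(0, N) else
      pmin(1, pmax(0, as.numeric(sweep(X, 2L, a) %*% ab) / len2))
    proj <- matrix(a, N, ncol(X), byrow = TRUE) + outer(t, ab)
    res <- rowSums((X - proj)^2)
    upd <- res < best_res # strict: ties keep the lower edge index
    best_res[upd] <- res[upd]
    best_edge[upd] <- e
    best_t[upd] <- t[upd]
    best_xy[upd, ] <- proj[upd, , drop = FALSE]
  }
  structure(list(edge = best_edge, t = best_t, coords = best_xy,
                 residual = best_res),
            class = "graph_projection")
}

graph_as_igraph <- function(graph, positions) {
  ig <- igraph::graph_from_edgelist(graph$edges, directed = FALSE)
  ig <- igraph::add_vertices(ig, max(0L, graph$n_nodes -
                                       igraph::vcount(ig)))
  igraph::E(ig)$weight <- edge_lengths(graph, positions)
  ig
}

#' Pseudotime along a fitted graph
#'
#' Pseudotime of a data point is the geodesic distance, measured along the
#' embedded graph edges, from a root node to the point's projection: the
#' shortest-path distance to one end of the projection edge plus the offset
#' along that edge, taking the cheaper of the two orientations (which also
#' resolves the antipode ambiguity on cycles, towards the lower-index end on
#' exact ties). On a disconnected graph, each component is measured from its
#' own root (the given root for its component; the lowest-index leaf, or
#' lowest-index node, otherwise) and the component id is reported.
#'
#' @param result a `principal_graph`.
#' @param projection a `graph_projection` of the points (see
#'   [project_points()]); computed from `X` if missing.
#' @param root root node index; defaults to the lowest-index leaf (lowest
#'   index node if the graph has no leaf).
#' @param X data matrix, only needed when `projection` is missing.
#' @return data frame with columns `pseudotime` and `component`.
#' @export
pseudotime <- function(result, projection = NULL, root = NULL, X = NULL) {
  graph <- result$graph
  pos <- result$positions
  if (is.null(projection)) {
    if (is.null(X)) stop("supply either `projection` or `X`")
    projection <- project_points(X, result)
  }
  deg <- node_degrees(graph)
  if (is.null(root)) {
    leaves <- which(deg == 1L)
    root <- if (length(leaves)) min(leaves) else 1L
  }
  ig <- graph_as_igraph(graph, pos)
  comp <- igraph::components(ig)$membership
  # one root per component
  roots <- integer(max(comp))
  for (cc in seq_len(max(comp))) {
    nodes <- which(comp == cc)
    if (comp[root] == cc) {
      roots[cc] <- root
    } else {
      lv <- nodes[deg[nodes] == 1L]
      roots[cc] <- if (length(lv)) min(lv) else min(nodes)
    }
  }
  D <- igraph::distances(ig, v = roots, weights = igraph::E(ig)$weight)
  node_dist <- numeric(graph$n_nodes)
  for (cc in seq_len(max(comp)))
    node_dist[comp == cc] <- D[cc, comp == cc]

  lens <- edge_lengths(graph, pos)
  pt <- numeric(length(projection$edge))
  for (i in seq_along(pt)) {
    e <- projection$edge[i]
    if (is.na(e)) { pt[i] <- 0; next }
    u <- graph$edges[e, 1L]; v <- graph$edges[e, 2L]
    t <- projection$t[i]
    pt[i] <- min(node_dist[u] + t * lens[e],
                 node_dist[v] + (1 - t) * lens[e])
  }
  point_comp <- ifelse(is.na(projection$edge), 1L,
                       comp[graph$edges[pmax(projection$edge, 1L), 1L]])
  data.frame(pseudotime = pt, component = point_comp)
}

#' Decompose a graph into branches
#'
#' A branch is a maximal path whose internal nodes all have degree 2,
#' delimited by nodes of degree different from 2 (leaves and branching
#' points). A pure cycle with no such delimiter forms a single closed
#' branch. Branches partition the edge set.
#'
#' @param result a `principal_graph` (or list with `graph`).
#' @return a list of class `branch_decomposition` with `branches` (list of
#'   ordered node-index paths), and `edge_branch` (branch id per edge).
#' @export
decompose_branches <- function(result) {
  graph <- result$graph
  deg <- node_degrees(graph)
  E <- nrow(graph$edges)
  adj <- adjacency_list(graph)
  edge_id <- function(a, b) find_edge(graph, a, b)
  edge_branch <- rep(NA_integer_, E)
  branches <- list()

  walk <- function(start, nxt) {
    # follow the chain of degree-2 nodes starting with edge (start, nxt)
    path <- c(start, nxt)
    repeat {
      e <- edge_id(path[length(path) - 1L], path[length(path)])
      edge_branch[e] <<- length(branches) + 1L
      cur <- path[length(path)]
      if (deg[cur] != 2L || cur == start) break
      nbs <- adj[[cur]]
      nxt2 <- setdiff(nbs, path[length(path) - 1L])
      if (length(nxt2) == 0L) break
      path <- c(path, nxt2[1L])
    }
    path
  }

  anchors <- which(deg != 2L & deg > 0L)
  for (a in anchors) {
    for (nb in adj[[a]]) {
      e <- edge_id(a, nb)
      if (!is.na(edge_branch[e])) next
      branches[[length(branches) + 1L]] <- walk(a, nb)
    }
  }
  # leftover pure cycles (every node degree 2)
  for (e in seq_len(E)) {
    if (!is.na(edge_branch[e])) next
    branches[[length(branches) + 1L]] <-
      walk(graph$edges[e, 1L], graph$edges[e, 2L])
  }
  structure(list(branches = branches, edge_branch = edge_branch),
            class = "branch_decomposition")
}

#' Label points by the branch they project onto
#'
#' @param decomposition a `branch_decomposition`.
#' @param projection a `graph_projection`.
#' @return integer vector of branch ids (NA for points projected onto an
#'   edgeless graph).
#' @export
branch_labels <- function(decomposition, projection) {
  ifelse(is.na(projection$edge), NA_integer_,
         decomposition$edge_branch[pmax(projection$edge, 1L)])
}

#' Fraction of variance explained by a fitted graph
#'
#' `FVE` is the fraction of total data variance explained by projecting
#' points onto their nearest graph node; `FVEP` is the (never smaller)
#' fraction explained by projecting onto the closest edge segment.
#'
#' @param X data matrix.
#' @param result a `principal_graph`.
#' @param projection optional precomputed `graph_projection`.
#' @return list with elements `FVE` and `FVEP`.
#' @export
explained_variance <- function(X, result, projection = NULL) {
  X <- as.matrix(X)
  if (is.null(projection)) projection <- project_points(X, result)
  part <- partition_data(X, result$positions, Inf)
  tv <- sum(sweep(X, 2L, colMeans(X))^2)
  if (tv == 0) return(list(FVE = 1, FVEP = 1))
  list(FVE = 1 - sum(part$distance^2) / tv,
       FVEP = 1 - sum(projection$residual) / tv)
}
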