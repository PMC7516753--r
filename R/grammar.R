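#' @name grammar
#' @title Graph-grammar rewriting operations
#'
#' @description
#' The topology of an elastic principal graph is learned by repeatedly
#' applying a small set of local graph-rewriting rules ("graph grammar") and
#' keeping the energetically best candidate. Four operations are provided:
#' `bisect_edge`, `add_node_to_node` (the growing grammar) and `remove_leaf`,
#' `shrink_internal_edge` (the shrinking grammar). Every operation returns a
#' candidate: the rewritten elastic graph together with the updated node
#' positions, ready to be re-optimized with [fit_graph()].
#'
#' Elasticity bookkeeping follows the rewriting rules exactly: bisected
#' half-edges inherit the parent edge modulus, a node added to a leaf copies
#' the neighbouring edge/star moduli, removing a leaf zeroes the mu of a
#' neighbour that becomes a leaf, and shrinking an internal edge averages the
#' two star moduli. A node that becomes a 2-star centre through `bisect_edge`
#' receives `default_mu`.
NULL

new_candidate <- function(graph, positions, op_label) {
  positions <- as.matrix(positions)
  dimnames(positions) <- NULL
  list(graph = graph, positions = positions, op_label = op_label)
}

replace_graph_fields <- function(graph, edges, lambdas, mus, n_nodes) {
  if (nrow(edges) > 0L) {
    flip <- edges[, 1L] > edges[, 2L]
    edges[flip, ] <- edges[flip, c(2L, 1L), drop = FALSE]
    ord <- order(edges[, 1L], edges[, 2L])
    edges <- edges[ord, , drop = FALSE]
    lambdas <- lambdas[ord]
  }
  g <- structure(
    list(n_nodes = as.integer(n_nodes), edges = edges,
         lambdas = lambdas, mus = mus, alpha = graph$alpha),
    class = "elastic_graph")
  validate_elastic_graph(g)
  g
}

find_edge <- function(graph, a, b) {
  lo <- min(a, b); hi <- max(a, b)
  which(graph$edges[, 1L] == lo & graph$edges[, 2L] == hi)
}

#' Bisect an edge
#'
#' Removes edge \{A, B\}, adds a new node C connected to both A and B. Both
#' half-edges inherit the stretching modulus of \{A, B\}, and C is placed at
#' the midpoint of A and B. C becomes the centre of a new 2-star and receives
#' `default_mu`.
#'
#' @param graph an `elastic_graph`.
#' @param positions node positions.
#' @param edge index of the edge to bisect.
#' @param default_mu bending modulus for the new 2-star centre.
#' @return a candidate (list with `graph`, `positions`, `op_label`).
#' @export
bisect_edge <- function(graph, positions, edge, default_mu = 0.1) {
  if (length(edge) != 1L || edge < 1L || edge > nrow(graph$edges))
    stop("no such edge")
  a <- graph$edges[edge, 1L]; b <- graph$edges[edge, 2L]
  new_id <- graph$n_nodes + 1L
  edges <- rbind(graph$edges[-edge, , drop = FALSE],
                 c(a, new_id), c(new_id, b))
  lam <- graph$lambdas[edge]
  lambdas <- c(graph$lambdas[-edge], lam, lam)
  mus <- c(graph$mus, default_mu)
  g <- replace_graph_fields(graph, edges, lambdas, mus, new_id)
  pos <- rbind(positions, (positions[a, ] + positions[b, ]) / 2)
  new_candidate(g, pos, sprintf("bisect_edge(%d-%d)", a, b))
}

#' Add a node to a node
#'
#' Adds a new node C and the edge \{A, C\}. If A is a leaf, C is placed at
#' the same distance and direction as the edge from A's neighbour to A (the
#' branch is extrapolated), the new edge copies that edge's modulus, and the
#' new 2-star centred at A copies the mu of the neighbour's star (or
#' `default_mu` if the graph has a single edge). If A is internal, the new
#' edge gets the mean modulus of A's star edges, A's mu is unchanged, and C
#' is placed at the mean of the data points assigned to A (or, when A has no
#' assigned points, just off A along its least-stretched incident edge).
#'
#' @param graph an `elastic_graph`.
#' @param positions node positions.
#' @param node index of the node A to grow from.
#' @param X data matrix (used to place C for internal A).
#' @param partition `graph_partition` of `X` onto `positions`.
#' @param default_mu fallback bending modulus.
#' @return a candidate.
#' @export
add_node_to_node <- function(graph, positions, node, X = NULL,
                             partition = NULL, default_mu = 0.1) {
  if (length(node) != 1L || node < 1L || node > graph$n_nodes)
    stop("no such node")
  deg <- node_degrees(graph)
  adj <- adjacency_list(graph)
  new_id <- graph$n_nodes + 1L
  inc <- which(graph$edges[, 1L] == node | graph$edges[, 2L] == node)

  if (deg[node] == 1L) {
    nb <- adj[[node]]
    lam_new <- graph$lambdas[inc]
    mu_new <- if (nrow(graph$edges) == 1L) default_mu else graph$mus[nb]
    mus <- c(graph$mus, 0)
    mus[node] <- mu_new
    pos_new <- positions[node, ] + (positions[node, ] - positions[nb, ])
  } else if (deg[node] >= 2L) {
    lam_new <- mean(graph$lambdas[inc])
    mus <- c(graph$mus, 0)
    assigned <- if (!is.null(partition))
      which(partition$assignment == node & !partition$trimmed) else integer(0)
    if (length(assigned) > 0L && !is.null(X)) {
      pos_new <- colMeans(as.matrix(X)[assigned, , drop = FALSE])
    } else {
      # no data charged to A: nudge off A along its least-stretched edge
      lens <- sqrt(rowSums((positions[graph$edges[inc, 1L], , drop = FALSE] -
                            positions[graph$edges[inc, 2L], , drop = FALSE])^2))
      i <- inc[which.min(lens)]
      other <- setdiff(graph$edges[i, ], node)
      dir <- positions[node, ] - positions[other, ]
      nd <- sqrt(sum(dir^2))
      if (nd == 0) dir <- rep(1 / sqrt(ncol(positions)), ncol(positions))
      else dir <- dir / nd
      pos_new <- positions[node, ] + dir * max(min(lens), 1e-8) * 0.1
    }
  } else { # isolated node
    lam_new <- if (nrow(graph$edges) > 0L) mean(graph$lambdas) else 0.01
    mus <- c(graph$mus, 0)
    pos_new <- positions[node, ] + 1e-8
  }

  edges <- rbind(graph$edges, c(node, new_id))
  lambdas <- c(graph$lambdas, lam_new)
  g <- replace_graph_fields(graph, edges, lambdas, mus, new_id)
  pos <- rbind(positions, pos_new)
  new_candidate(g, pos, sprintf("add_node_to_node(%d)", node))
}

#' Remove a leaf node
#'
#' Removes a degree-1 node and its edge. If the neighbour was the centre of a
#' 2-star it becomes a leaf and its star modulus is zeroed; larger stars keep
#' their modulus. All other node positions are unchanged.
#'
#' @param graph an `elastic_graph`.
#' @param positions node positions.
#' @param node index of the leaf to remove.
#' @return a candidate.
#' @export
remove_leaf <- function(graph, positions, node) {
  deg <- node_degrees(graph)
  if (length(node) != 1L || node < 1L || node > graph$n_nodes ||
      deg[node] != 1L)
    stop("node is not a leaf")
  inc <- which(graph$edges[, 1L] == node | graph$edges[, 2L] == node)
  nb <- setdiff(graph$edges[inc, ], node)
  mus <- graph$mus
  if (deg[nb] == 2L) mus[nb] <- 0
  edges <- graph$edges[-inc, , drop = FALSE]
  keep <- setdiff(seq_len(graph$n_nodes), node)
  remap <- integer(graph$n_nodes)
  remap[keep] <- seq_along(keep)
  edges[] <- remap[edges]
  g <- replace_graph_fields(graph, edges, graph$lambdas[-inc], mus[keep],
                            graph$n_nodes - 1L)
  new_candidate(g, positions[keep, , drop = FALSE],
                sprintf("remove_leaf(%d)", node))
}

#' Shrink an internal edge
#'
#' For an edge \{A, B\} with both endpoints of degree > 1: removes the edge
#' and node A, reattaches A's other edges to B, places B at the midpoint of A
#' and B, and sets B's star modulus to the mean of the former A and B star
#' moduli. Duplicate edges arising in cyclic graphs are collapsed to a single
#' edge keeping the largest modulus.
#'
#' @param graph an `elastic_graph`.
#' @param positions node positions.
#' @param edge index of the internal edge to shrink.
#' @return a candidate.
#' @export
shrink_internal_edge <- function(graph, positions, edge) {
  if (length(edge) != 1L || edge < 1L || edge > nrow(graph$edges))
    stop("no such edge")
  a <- graph$edges[edge, 1L]; b <- graph$edges[edge, 2L]
  deg <- node_degrees(graph)
  if (deg[a] <= 1L || deg[b] <= 1L)
    stop("edge is not internal (both endpoints must have degree > 1)")

  edges <- graph$edges[-edge, , drop = FALSE]
  lambdas <- graph$lambdas[-edge]
  # reattach A's remaining edges to B
  edges[edges == a] <- b
  # collapse duplicates, keep max lambda (conservative stiffness)
  key <- paste(pmin(edges[, 1L], edges[, 2L]), pmax(edges[, 1L], edges[, 2L]))
  if (anyDuplicated(key)) {
    lam_by <- tapply(lambdas, key, max)
    first <- !duplicated(key)
    edges <- edges[first, , drop = FALSE]
    lambdas <- as.numeric(lam_by[key[first]])
  }
  mus <- graph$mus
  mus[b] <- (graph$mus[a] + graph$mus[b]) / 2
  positions[b, ] <- (positions[a, ] + positions[b, ]) / 2

  keep <- setdiff(seq_len(graph$n_nodes), a)
  remap <- integer(graph$n_nodes)
  remap[keep] <- seq_along(keep)
  edges[] <- remap[edges]
  mus <- mus[keep]
  # a merged node may end up a leaf (e.g., shrinking a triangle edge)
  new_deg <- tabulate(edges, nbins = graph$n_nodes - 1L)
  mus[new_deg < 2L] <- 0
  g <- replace_graph_fields(graph, edges, lambdas, mus, graph$n_nodes - 1L)
  new_candidate(g, positions[keep, , drop = FALSE],
                sprintf("shrink_internal_edge(%d-%d)", a, b))
}

#' Generate all candidate graphs for a grammar set
#'
#' Applies every operation in `grammar` to every admissible graph element.
#' With a finite `max_candidates` k, the reduced search of the scalable
#' variant is used: `bisect_edge` is restricted to the k longest edges (at
#' the current embedding) and `add_node_to_node` to the k nodes carrying the
#' most data points; ties are broken by element index. `remove_leaf` and
#' `shrink_internal_edge` are never restricted. Candidates that duplicate an
#' earlier candidate's topology and positions are dropped.
#'
#' @param graph an `elastic_graph`.
#' @param positions node positions.
#' @param grammar character vector of operation names, a subset of
#'   `c("bisect_edge", "add_node_to_node", "remove_leaf",
#'   "shrink_internal_edge")`.
#' @param X data matrix (for `add_node_to_node` placement and node loads).
#' @param partition `graph_partition` of `X` onto `positions`.
#' @param max_candidates per-operation candidate budget k (default unlimited).
#' @param default_mu bending modulus assigned to newly formed 2-star centres.
#' @return list of candidates (possibly empty).
#' @export
generate_candidates <- function(graph, positions, grammar, X = NULL,
                                partition = NULL, max_candidates = Inf,
                                default_mu = 0.1) {
  known_ops <- c("bisect_edge", "add_node_to_node", "remove_leaf",
                 "shrink_internal_edge")
  if (length(grammar) == 0L || !all(grammar %in% known_ops))
    stop("grammar must be a non-empty subset of: ",
         paste(known_ops, collapse = ", "))
  deg <- node_degrees(graph)
  cands <- list()
  seen <- new.env(parent = emptyenv())

  push <- function(cand) {
    key <- paste(c(cand$graph$n_nodes, t(cand$graph$edges),
                   signif(cand$positions, 12)), collapse = ",")
    if (is.null(seen[[key]])) {
      seen[[key]] <- TRUE
      cands[[length(cands) + 1L]] <<- cand
    }
  }

  for (op in grammar) {
    if (op == "bisect_edge") {
      idx <- seq_len(nrow(graph$edges))
      if (is.finite(max_candidates) && length(idx) > max_candidates) {
        lens <- edge_lengths(graph, positions)
        idx <- idx[order(-lens, idx)][seq_len(max_candidates)]
        idx <- sort(idx)
      }
      for (e in idx) push(bisect_edge(graph, positions, e, default_mu))
    } else if (op == "add_node_to_node") {
      idx <- seq_len(graph$n_nodes)
      if (is.finite(max_candidates) && length(idx) > max_candidates) {
        loads <- numeric(graph$n_nodes)
        if (!is.null(partition)) {
          keep <- !partition$trimmed
          tab <- table(partition$assignment[keep])
          loads[as.integer(names(tab))] <- as.numeric(tab)
        }
        idx <- idx[order(-loads, idx)][seq_len(max_candidates)]
        idx <- sort(idx)
      }
      for (v in idx)
        push(add_node_to_node(graph, positions, v, X, partition, default_mu))
    } else if (op == "remove_leaf") {
      if (graph$n_nodes > 2L)
        for (v in which(deg == 1L)) push(remove_leaf(graph, positions, v))
    } else if (op == "shrink_internal_edge") {
      internal <- which(deg[graph$edges[, 1L]] > 1L &
                        deg[graph$edges[, 2L]] > 1L)
      for (e in internal) push(shrink_internal_edge(graph, positions, e))
    }
  }
  cands
}
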