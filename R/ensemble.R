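#' Fit a bootstrap ensemble of principal graphs
#'
#' Runs [learn_graph()] `k` times, each time on a random subsample of
#' `ceiling(p * N)` points drawn without replacement. Every member gets its
#' own seed derived reproducibly from the master seed, so the whole ensemble
#' is a pure function of `(X, config, k, p, seed)`.
#'
#' @param X data matrix.
#' @param config a [learn_config()] shared by all members.
#' @param k number of ensemble members.
#' @param p subsample fraction in (0, 1].
#' @param seed master seed.
#' @return an object of class `graph_ensemble`: list with `members` (list of
#'   `principal_graph`), `subsamples` (row indices per member), and the
#'   settings.
#' @export
fit_ensemble <- function(X, config, k = 20L, p = 0.9, seed = 1L) {
  X <- as.matrix(X)
  stopifnot(k >= 1L, p > 0, p <= 1)
  N <- nrow(X)
  n_sub <- ceiling(p * N)
  set.seed(seed)
  member_seeds <- sample.int(2147483646L, k)
  subsamples <- lapply(seq_len(k), function(i) sort(sample.int(N, n_sub)))
  members <- vector("list", k)
  for (i in seq_len(k)) {
    cfg <- config
    cfg$seed <- member_seeds[i]
    members[[i]] <- learn_graph(X[subsamples[[i]], , drop = FALSE], cfg)
  }
  structure(list(members = members, subsamples = subsamples, k = k, p = p,
                 seed = seed, config = config),
            class = "graph_ensemble")
}

#' Consensus-graph parameters
#'
#' @param min_nodes_per_cluster minimum number of pooled member nodes a node
#'   cluster needs to enter the consensus graph; default `max(2,
#'   ceiling(0.25 * k))`, resolved at build time.
#' @param min_edge_support minimum number of member edges an aggregated
#'   consensus edge needs; default `ceiling(0.25 * k)`.
#' @param length_bounds allowed consensus edge lengths, relative to the
#'   median consensus edge length; edges outside the bounds are removed when
#'   this does not disconnect their component.
#' @param cluster_height agglomeration distance threshold for matching member
#'   nodes into clusters; default (NULL) is half the median member edge
#'   length, so that corresponding nodes across members merge while adjacent
#'   nodes of one member stay separate.
#' @param refit re-optimize the consensus embedding with [fit_graph()] on the
#'   full data (requires `X` in [build_consensus()]).
#' @return a list of class `consensus_params`.
#' @export
consensus_params <- function(min_nodes_per_cluster = NULL,
                             min_edge_support = NULL,
                             length_bounds = c(0.1, 3),
                             cluster_height = NULL, refit = FALSE) {
  stopifnot(length(length_bounds) == 2L, all(length_bounds > 0),
            length_bounds[1L] < length_bounds[2L])
  structure(list(min_nodes_per_cluster = min_nodes_per_cluster,
                 min_edge_support = min_edge_support,
                 length_bounds = length_bounds,
                 cluster_height = cluster_height, refit = refit),
            class = "consensus_params")
}

#' Build a consensus principal graph from an ensemble
#'
#' Summarizes a graph ensemble into a single consensus graph: (1) the member
#' node positions are pooled and (2) matched into clusters by agglomerative
#' (average-linkage) clustering cut at half the median member edge length,
#' dropping clusters with too few member nodes; (3) consensus edges connect
#' cluster pairs that aggregate at least `min_edge_support` member edges;
#' (4) isolated consensus nodes are removed; (5) consensus edges shorter or
#' longer than the length bounds are deleted, skipping any deletion that
#' would disconnect the touched component. The consensus can recover
#' topological features (such as loops) absent from every single member.
#' Optionally the consensus embedding is re-optimized against the data.
#'
#' @param ensemble a `graph_ensemble` (or plain list of `principal_graph`).
#' @param params a [consensus_params()] object.
#' @param X full data matrix; required when `params$refit` is `TRUE`.
#' @return a `principal_graph`-like consensus result, with `node_support`
#'   (member nodes per consensus node) and `edge_support` attached.
#' @export
build_consensus <- function(ensemble, params = consensus_params(), X = NULL) {
  members <- if (inherits(ensemble, "graph_ensemble")) ensemble$members else
    ensemble
  k <- length(members)
  if (k == 0L) stop("ensemble is empty")
  min_cluster <- params$min_nodes_per_cluster %||% max(2L, ceiling(0.25 * k))
  min_support <- params$min_edge_support %||% ceiling(0.25 * k)

  pooled <- do.call(rbind, lapply(members, function(m) m$positions))
  offsets <- cumsum(c(0L, vapply(members, function(m) m$graph$n_nodes,
                                 integer(1L))))
  member_edge_lengths <- unlist(lapply(members, function(m)
    edge_lengths(m$graph, m$positions)))
  height <- params$cluster_height %||%
    (0.5 * stats::median(member_edge_lengths))

  if (nrow(pooled) > 1L) {
    hc <- stats::hclust(stats::dist(pooled), method = "average")
    cl <- stats::cutree(hc, h = height)
  } else cl <- 1L

  sizes <- tabulate(cl)
  kept <- which(sizes >= min_cluster)
  if (length(kept) == 0L)
    stop(sprintf(paste0("empty consensus: no node cluster reached ",
                        "min_nodes_per_cluster = %d (largest had %d)"),
                 min_cluster, max(sizes)))
  cons_id <- integer(max(cl))
  cons_id[kept] <- seq_along(kept)
  positions <- do.call(rbind, lapply(kept, function(cc)
    colMeans(pooled[cl == cc, , drop = FALSE])))
  node_support <- sizes[kept]

  # aggregate member edges over cluster pairs
  pair_count <- new.env(parent = emptyenv())
  for (i in seq_len(k)) {
    e <- members[[i]]$graph$edges
    if (nrow(e) == 0L) next
    c1 <- cl[e[, 1L] + offsets[i]]
    c2 <- cl[e[, 2L] + offsets[i]]
    for (r in seq_len(nrow(e))) {
      a <- cons_id[c1[r]]; b <- cons_id[c2[r]]
      if (a == 0L || b == 0L || a == b) next
      key <- paste(min(a, b), max(a, b))
      pair_count[[key]] <- (pair_count[[key]] %||% 0L) + 1L
    }
  }
  keys <- sort(ls(pair_count))
  support <- vapply(keys, function(kk) pair_count[[kk]], integer(1L))
  keep_e <- support >= min_support
  if (!any(keep_e))
    stop(sprintf(paste0("empty consensus: no aggregated edge reached ",
                        "min_edge_support = %d"), min_support))
  edges <- do.call(rbind, lapply(strsplit(keys[keep_e], " "), as.integer))
  edge_support <- support[keep_e]

  # (4) drop isolated nodes
  used <- sort(unique(as.integer(edges)))
  remap <- integer(nrow(positions))
  remap[used] <- seq_along(used)
  edges[] <- remap[edges]
  positions <- positions[used, , drop = FALSE]
  node_support <- node_support[used]

  # (5) length filtering, preserving connectivity: repeatedly drop the most
  # out-of-range edge whose removal is not a bridge
  lens <- sqrt(rowSums((positions[edges[, 1L], , drop = FALSE] -
                        positions[edges[, 2L], , drop = FALSE])^2))
  med <- stats::median(lens)
  bounds <- params$length_bounds * med
  repeat {
    if (nrow(edges) <= 1L) break
    bad <- which(lens < bounds[1L] | lens > bounds[2L])
    if (length(bad) == 0L) break
    bad <- bad[order(-abs(log(pmax(lens[bad], 1e-300) / med)))]
    ig <- igraph::graph_from_edgelist(edges, directed = FALSE)
    bridge_ids <- as.integer(igraph::bridges(ig))
    removable <- bad[!vapply(bad, function(b)
      igraph::get_edge_ids(ig, as.integer(edges[b, ])) %in% bridge_ids,
      logical(1L))]
    if (length(removable) == 0L) break
    keep <- setdiff(seq_len(nrow(edges)), removable[1L])
    edges <- edges[keep, , drop = FALSE]
    lens <- lens[keep]
    edge_support <- edge_support[keep]
  }

  # drop nodes isolated by the length filter
  used <- sort(unique(as.integer(edges)))
  remap <- integer(nrow(positions))
  remap[used] <- seq_along(used)
  edges[] <- remap[edges]
  positions <- positions[used, , drop = FALSE]
  node_support <- node_support[used]

  cfg <- if (inherits(ensemble, "graph_ensemble")) ensemble$config else
    members[[1L]]$config
  graph <- elastic_graph(edges, n_nodes = nrow(positions),
                         lambda = cfg$lambda %||% 0.01,
                         mu = cfg$mu %||% 0.1, alpha = cfg$alpha %||% 0)
  if (isTRUE(params$refit)) {
    if (is.null(X)) stop("refit = TRUE requires the data matrix X")
    fp <- fit_params(trimming_radius = cfg$trimming_radius %||% Inf,
                     max_iter = cfg$max_iter %||% 200L,
                     eps = cfg$eps %||% 1e-3)
    if (identical(fp$trimming_radius, "auto"))
      fp$trimming_radius <- suggest_trimming_radius(as.matrix(X))
    fit <- fit_graph(as.matrix(X), graph, positions, fp)
    positions <- fit$positions
  }

  res <- structure(
    list(graph = graph, positions = positions,
         energy = if (!is.null(X))
           energy_report(as.matrix(X), graph, positions) else NULL,
         partition = if (!is.null(X))
           partition_data(as.matrix(X), positions) else NULL,
         history = data.frame(), config = cfg,
         trimming_radius = Inf,
         node_support = node_support, edge_support = edge_support),
    class = "principal_graph")
  res$config$mode <- "consensus"
  res
}

#' Confidence intervals for branching-point positions
#'
#' For every branching point (node of degree >= 3) of a reference graph,
#' matches the branching points of each ensemble member to their nearest
#' reference branching point (within `threshold`), projects the matched
#' member positions onto the reference graph, and summarizes their
#' pseudotime (path coordinate from `root`) as a 2.5-97.5 percentile
#' interval. The support is the fraction of members contributing a match.
#'
#' @param ensemble a `graph_ensemble` or list of `principal_graph` members.
#' @param reference a `principal_graph` whose branching points are assessed.
#' @param root root node for the path coordinate (default: lowest-index
#'   leaf).
#' @param threshold maximum matching distance; default twice the median
#'   reference edge length.
#' @return data frame with one row per reference branching point: `node`,
#'   `pt` (its own pseudotime), `pt_low`, `pt_high`, `support`, `n_matched`.
#' @export
branching_confidence <- function(ensemble, reference, root = NULL,
                                 threshold = NULL) {
  members <- if (inherits(ensemble, "graph_ensemble")) ensemble$members else
    ensemble
  k <- length(members)
  deg <- node_degrees(reference$graph)
  bp <- which(deg >= 3L)
  if (length(bp) == 0L)
    return(data.frame(node = integer(0), pt = numeric(0),
                      pt_low = numeric(0), pt_high = numeric(0),
                      support = numeric(0), n_matched = integer(0)))
  threshold <- threshold %||%
    (2 * stats::median(edge_lengths(reference$graph, reference$positions)))

  ref_bp_pos <- reference$positions[bp, , drop = FALSE]
  # path coordinate of the reference branching points themselves
  self_proj <- project_points(ref_bp_pos, reference)
  self_pt <- pseudotime(reference, self_proj, root = root)$pseudotime

  vals <- vector("list", length(bp))
  matched_members <- integer(length(bp))
  for (m in members) {
    mdeg <- node_degrees(m$graph)
    mb <- which(mdeg >= 3L)
    if (length(mb) == 0L) next
    mpos <- m$positions[mb, , drop = FALSE]
    d <- sqrt(squared_distances(mpos, ref_bp_pos))
    # each member branching point goes to its nearest reference point
    assign <- max.col(-d, ties.method = "first")
    ok <- d[cbind(seq_len(nrow(d)), assign)] <= threshold
    if (!any(ok)) next
    proj <- project_points(mpos[ok, , drop = FALSE], reference)
    pt <- pseudotime(reference, proj, root = root)$pseudotime
    hit <- logical(length(bp))
    for (i in which(ok)) {
      j <- assign[i]
      vals[[j]] <- c(vals[[j]], pt[match(i, which(ok))])
      hit[j] <- TRUE
    }
    matched_members <- matched_members + hit
  }

  data.frame(
    node = bp,
    pt = self_pt,
    pt_low = vapply(vals, function(v)
      if (length(v)) unname(stats::quantile(v, 0.025)) else NA_real_,
      numeric(1L)),
    pt_high = vapply(vals, function(v)
      if (length(v)) unname(stats::quantile(v, 0.975)) else NA_real_,
      numeric(1L)),
    support = matched_members / k,
    n_matched = vapply(vals, length, integer(1L)))
}
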