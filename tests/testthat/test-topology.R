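test_that("PC1 initialization aligns with the dominant axis", {
  set.seed(21)
  X <- cbind(rnorm(300, sd = 3), rnorm(300, sd = 1))
  init <- initialize_pc1(X)
  dir <- init$positions[2, ] - init$positions[1, ]
  dir <- dir / sqrt(sum(dir^2))
  pc1 <- eigen(cov(X), symmetric = TRUE)$vectors[, 1]
  expect_lt(acos(min(1, abs(sum(dir * pc1)))), 1e-3)
  # exactly collinear data stays on the line
  Xl <- cbind(1:10, 2 * (1:10) + 1)
  initl <- initialize_pc1(Xl)
  resid <- initl$positions[, 2] - (2 * initl$positions[, 1] + 1)
  expect_equal(resid, c(0, 0), tolerance = 1e-8)
  expect_error(initialize_pc1(Xl[1, , drop = FALSE]), "two data points")
})

test_that("density initialization starts in the densest region", {
  set.seed(22)
  big <- matrix(rnorm(200, sd = 0.2), 100, 2)
  small <- matrix(rnorm(20, mean = 5, sd = 0.2), 10, 2)
  X <- rbind(big, small)
  init <- initialize_density(X, radius = 1)
  # counting oracle: the chosen point must have the max neighbour count
  counts <- rowSums(as.matrix(dist(X)) <= 1)
  chosen <- which(apply(X, 1, function(r)
    all(r == init$positions[1, ])))[1]
  expect_equal(unname(counts[chosen]), max(counts))
  expect_lt(sqrt(sum(init$positions[1, ]^2)), 2) # inside the big cluster
  # second node is the nearest distinct point
  d <- sqrt(rowSums(sweep(X, 2, init$positions[1, ])^2))
  d[d == 0] <- Inf
  expect_equal(sqrt(sum((init$positions[2, ] - init$positions[1, ])^2)),
               min(d))
})

test_that("degenerate density initialization errors; huge radius is deterministic", {
  X <- matrix(1, 5, 2) # all identical: no distinct neighbour
  expect_error(initialize_density(X, radius = 1), "distinct")
  set.seed(23)
  Y <- matrix(runif(20), 10, 2)
  i1 <- initialize_density(Y, radius = 100)
  i2 <- initialize_density(Y, radius = 100)
  expect_equal(i1$positions, i2$positions) # all counts tie -> lowest index
  expect_equal(i1$positions[1, ], Y[1, ])
})

test_that("MST initialization over three separated clusters matches brute force", {
  set.seed(24)
  centers <- rbind(c(0, 0), c(10, 0), c(10, 8))
  X <- do.call(rbind, lapply(1:3, function(i)
    sweep(matrix(rnorm(60, sd = 0.3), 30, 2), 2, centers[i, ], "+")))
  init <- initialize_mst(X, n_centroids = 3)
  expect_equal(init$graph$n_nodes, 3L)
  expect_equal(nrow(init$graph$edges), 2L)
  # brute-force MST over 3 points: keep the two shortest of three edges
  D <- as.matrix(dist(init$positions))
  pairs <- rbind(c(1, 2), c(1, 3), c(2, 3))
  lens <- D[pairs]
  expected <- pairs[order(lens)[1:2], , drop = FALSE]
  canon <- function(e) e[order(e[, 1], e[, 2]), , drop = FALSE]
  expect_equal(canon(init$graph$edges),
               canon(t(apply(expected, 1, sort))))

  init2 <- initialize_mst(X, n_centroids = 2)
  expect_equal(nrow(init2$graph$edges), 1L)
  expect_warning(initialize_mst(matrix(1, 6, 2)), "degenerate")
})

test_that("curve mode grows a simple path", {
  set.seed(25)
  t <- seq(0, pi, length.out = 30)
  X <- cbind(cos(t), sin(t)) + matrix(rnorm(60, sd = 0.05), 30, 2)
  pg <- learn_graph(X, learn_config(mode = "curve", n_nodes = 10, seed = 1))
  deg <- node_degrees(pg$graph)
  expect_equal(pg$graph$n_nodes, 10L)
  expect_equal(nrow(pg$graph$edges), 9L)
  expect_lte(max(deg), 2L)
  expect_equal(sum(deg == 1L), 2L) # a connected path
})

test_that("circle mode keeps a single cycle", {
  set.seed(26)
  t <- runif(150, 0, 2 * pi)
  X <- cbind(cos(t), sin(t)) + matrix(rnorm(300, sd = 0.05), 150, 2)
  pg <- learn_graph(X, learn_config(mode = "circle", n_nodes = 12, seed = 1))
  expect_equal(pg$graph$n_nodes, 12L)
  expect_equal(nrow(pg$graph$edges), 12L)
  expect_true(all(node_degrees(pg$graph) == 2L))
})

test_that("tree mode yields a connected acyclic graph", {
  set.seed(27)
  star <- generate_armed_star(n_points = 120, n_arms = 3, seed = 3)
  pg <- learn_graph(star$X, learn_config(mode = "tree", n_nodes = 8,
                                         alpha = 0.01, seed = 1))
  expect_true(all(pg$history$n_candidates >= 1L))
  # tree grammar closure: acyclic and connected at every accepted size
  expect_equal(nrow(pg$graph$edges), pg$graph$n_nodes - 1L)
  ig <- igraph::graph_from_edgelist(pg$graph$edges, directed = FALSE)
  expect_true(igraph::is_connected(ig))
})

test_that("leaf extension covers the extreme data projections", {
  set.seed(28)
  X <- cbind(seq(0, 1, length.out = 100), rnorm(100, sd = 0.01))
  pg <- learn_graph(X, learn_config(mode = "curve", n_nodes = 6, seed = 1))
  ext <- extend_leaves(pg, X, factor = 1)
  deg <- node_degrees(ext$graph)
  adj <- epgraph:::adjacency_list(ext$graph)
  part <- partition_data(X, ext$positions)
  for (leaf in which(deg == 1L)) {
    u <- ext$positions[leaf, ] - ext$positions[adj[[leaf]], ]
    u <- u / sqrt(sum(u^2))
    pts <- which(part$assignment == leaf)
    if (!length(pts)) next
    over <- (X[pts, , drop = FALSE] -
               matrix(ext$positions[leaf, ], length(pts), 2,
                      byrow = TRUE)) %*% u
    expect_lte(max(over), 1e-8) # nothing projects beyond the new leaf
  }
  # factor 0 is the identity
  same <- extend_leaves(pg, X, factor = 0)
  expect_equal(same$positions, pg$positions)
  # a leafless cycle is a no-op with a warning
  cyc <- manual_result(rbind(c(1, 2), c(2, 3), c(3, 1)),
                       rbind(c(0, 0), c(1, 0), c(0.5, 1)))
  expect_warning(extend_leaves(cyc, X), "no leaves")
})

test_that("appending extension nodes keeps one extra node per leaf", {
  set.seed(29)
  X <- cbind(seq(0, 1, length.out = 80), rnorm(80, sd = 0.01))
  pg <- learn_graph(X, learn_config(mode = "curve", n_nodes = 5, seed = 1))
  ext <- extend_leaves(pg, X, mode = "append", factor = 1)
  expect_equal(ext$graph$n_nodes, pg$graph$n_nodes + 2L)
})

test_that("edge pruning removes an unsupported branch and nothing else", {
  # a path carrying all the data plus one spurious empty branch
  pos <- rbind(c(0, 0), c(1, 0), c(2, 0), c(3, 0), c(1.5, 2))
  res <- manual_result(rbind(path_edges(4), c(2, 5)), pos)
  set.seed(30)
  X <- cbind(runif(120, 0, 3), rnorm(120, sd = 0.02))
  expect_identical(prune_edges(res, X, min_points = 0), res)
  pruned <- prune_edges(res, X, min_points = 5)
  expect_equal(pruned$graph$n_nodes, 4L)
  expect_equal(nrow(pruned$graph$edges), 3L)
  expect_lte(max(node_degrees(pruned$graph)), 2L)
})

test_that("a finite trimming radius yields a principal forest on separated clusters", {
  set.seed(31)
  c1 <- cbind(runif(120, 0, 1), rnorm(120, sd = 0.05))
  c2 <- cbind(runif(120, 4, 5), rnorm(120, sd = 0.05) + 3)
  X <- rbind(c1, c2)
  forest <- learn_forest(X, learn_config(mode = "curve", n_nodes = 6,
                                         trimming_radius = 0.4, seed = 1),
                         max_components = 4)
  expect_gte(length(forest), 2L)
  expect_gte(mean(attr(forest, "covered")), 0.99)
})
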