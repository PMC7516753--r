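test_that("point projection matches analytic results on a unit edge", {
  res <- manual_result(rbind(c(1, 2)), rbind(c(0, 0), c(1, 0)))
  proj <- project_points(rbind(c(0.3, 0.4), c(0, 0), c(1, 0), c(-1, 0)), res)
  expect_equal(proj$t, c(0.3, 0, 1, 0))
  expect_equal(proj$residual, c(0.16, 0, 0, 1))
  expect_equal(proj$coords[1, ], c(0.3, 0))
})

test_that("projection agrees with a dense-sampling oracle", {
  set.seed(51)
  pos <- random_positions(5, 3)
  res <- manual_result(path_edges(5), pos)
  X <- matrix(rnorm(30), 10, 3)
  proj <- project_points(X, res)
  # oracle: sample every edge densely and take the global minimum
  ts <- seq(0, 1, length.out = 20001)
  dense <- do.call(rbind, lapply(1:4, function(e) {
    a <- pos[e, ]; b <- pos[e + 1, ]
    outer(1 - ts, a) + outer(ts, b)
  }))
  d2 <- epgraph:::squared_distances(X, dense)
  expect_equal(proj$residual, apply(d2, 1, min), tolerance = 1e-7)
})

test_that("tie-breaking picks the lowest edge index", {
  # two parallel edges equidistant from the test point
  res <- manual_result(rbind(c(1, 2), c(3, 4)),
                       rbind(c(0, 1), c(1, 1), c(0, -1), c(1, -1)))
  proj <- project_points(matrix(c(0.5, 0), 1, 2), res)
  expect_equal(proj$edge, 1L)
})

test_that("pseudotime accumulates along a path from the root", {
  res <- manual_result(path_edges(3), rbind(c(0, 0), c(1, 0), c(2, 0)))
  X <- rbind(c(0, 0.1), c(1.5, 0.2), c(2, 0))
  proj <- project_points(X, res)
  pt <- pseudotime(res, proj, root = 1)
  expect_equal(pt$pseudotime, c(0, 1.5, 2))
})

test_that("pseudotime on a cycle never exceeds half the cycle length plus an edge", {
  n <- 8
  theta <- 2 * pi * (0:(n - 1)) / n
  pos <- cbind(cos(theta), sin(theta))
  edges <- rbind(cbind(1:(n - 1), 2:n), c(n, 1))
  res <- manual_result(edges, pos)
  set.seed(52)
  phi <- runif(60, 0, 2 * pi)
  X <- 1.05 * cbind(cos(phi), sin(phi))
  proj <- project_points(X, res)
  pt <- pseudotime(res, proj, root = 1)$pseudotime
  total <- sum(epgraph:::edge_lengths(res$graph, pos))
  expect_true(all(pt <= total / 2 + max(epgraph:::edge_lengths(res$graph,
                                                               pos)) + 1e-9))
  # oracle: geodesic distance computed by brute force over both arc
  # directions; nodes are uniformly spaced so node i sits at arc (i-1)*len
  len <- epgraph:::edge_lengths(res$graph, pos)[1]
  for (i in seq_along(pt)) {
    u <- res$graph$edges[proj$edge[i], 1]
    v <- res$graph$edges[proj$edge[i], 2]
    s <- if (v == u + 1) (u - 1) * len + proj$t[i] * len else
      (total - proj$t[i] * len) %% total # the closing edge (1, n)
    expect_equal(pt[i], min(s, total - s), tolerance = 1e-9)
  }
})

test_that("pseudotime is 1-Lipschitz along a shared edge", {
  set.seed(53)
  pos <- random_positions(6, 2)
  res <- manual_result(path_edges(6), pos)
  X <- matrix(rnorm(80), 40, 2)
  proj <- project_points(X, res)
  pt <- pseudotime(res, proj, root = 1)$pseudotime
  lens <- epgraph:::edge_lengths(res$graph, pos)
  for (e in unique(proj$edge)) {
    idx <- which(proj$edge == e)
    if (length(idx) < 2) next
    expect_lte(diff(range(pt[idx])), lens[e] + 1e-9)
  }
})

test_that("disconnected graphs report per-component pseudotime", {
  res <- manual_result(rbind(c(1, 2), c(3, 4)),
                       rbind(c(0, 0), c(1, 0), c(10, 0), c(11, 0)))
  X <- rbind(c(0.5, 0), c(10.5, 0))
  pt <- pseudotime(res, project_points(X, res), root = 1)
  expect_equal(pt$component, c(1L, 2L))
  expect_equal(pt$pseudotime, c(0.5, 0.5)) # each from its own root
})

test_that("branch decomposition splits at nodes of degree != 2", {
  path <- manual_result(path_edges(5), cbind(0:4, 0))
  expect_length(decompose_branches(path)$branches, 1L)

  star <- manual_result(rbind(c(1, 2), c(1, 3), c(1, 4)),
                        rbind(c(0, 0), c(1, 0), c(0, 1), c(-1, 0)))
  expect_length(decompose_branches(star)$branches, 3L)

  # Y-graph with subdivided arms still has exactly 3 branches
  yg <- manual_result(rbind(c(1, 2), c(2, 3), c(1, 4), c(4, 5), c(1, 6)),
                      rbind(c(0, 0), c(1, 0), c(2, 0), c(0, 1), c(0, 2),
                            c(-1, -1)))
  dec <- decompose_branches(yg)
  expect_length(dec$branches, 3L)
  expect_true(all(!is.na(dec$edge_branch)))

  # a pure cycle is a single closed branch
  cyc <- manual_result(rbind(c(1, 2), c(2, 3), c(3, 1)),
                       rbind(c(0, 0), c(1, 0), c(0.5, 1)))
  expect_length(decompose_branches(cyc)$branches, 1L)
})

test_that("branch labels are invariant under edge subdivision", {
  star <- manual_result(rbind(c(1, 2), c(1, 3), c(1, 4)),
                        rbind(c(0, 0), c(2, 0), c(0, 2), c(-2, 0)))
  set.seed(54)
  X <- rbind(cbind(runif(20, 0.3, 2), 0), cbind(0, runif(20, 0.3, 2)),
             cbind(-runif(20, 0.3, 2), 0))
  lab1 <- branch_labels(decompose_branches(star),
                        project_points(X, star))
  sub <- bisect_edge(star$graph, star$positions, 1)
  star2 <- manual_result(sub$graph$edges, sub$positions)
  lab2 <- branch_labels(decompose_branches(star2),
                        project_points(X, star2))
  # same partition of the points, up to branch renaming
  expect_equal(length(unique(paste(lab1, lab2))), 3L)
})

test_that("explained variance is 1 at the nodes and ordered FVE <= FVEP", {
  pos <- rbind(c(0, 0), c(1, 0), c(2, 1))
  res <- manual_result(path_edges(3), pos)
  ev <- explained_variance(pos, res)
  expect_equal(ev$FVE, 1)
  expect_equal(ev$FVEP, 1)

  set.seed(55)
  X <- matrix(rnorm(60), 30, 2)
  single <- manual_result(NULL, matrix(colMeans(X), 1, 2))
  ev1 <- explained_variance(X, single)
  expect_equal(ev1$FVE, 0, tolerance = 1e-12)

  res2 <- manual_result(path_edges(3), random_positions(3, 2))
  ev2 <- explained_variance(X, res2)
  expect_gte(ev2$FVEP, ev2$FVE)
  expect_lte(ev2$FVEP, 1)
})
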