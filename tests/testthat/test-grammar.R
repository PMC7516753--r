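test_that("bisecting an edge inserts the midpoint and copies the modulus", {
  g <- elastic_graph(rbind(c(1, 2)), lambda = 0.05, mu = 0.1)
  pos <- rbind(c(0, 0), c(2, 0))
  cand <- bisect_edge(g, pos, 1, default_mu = 0.1)
  expect_equal(cand$positions[3, ], c(1, 0))
  expect_equal(cand$graph$n_nodes, 3L)
  expect_equal(nrow(cand$graph$edges), 2L)
  expect_equal(cand$graph$lambdas, c(0.05, 0.05))
  expect_equal(cand$graph$mus[3], 0.1) # new 2-star centre
  expect_error(bisect_edge(g, pos, 5), "no such edge")
})

test_that("bisecting a cycle edge preserves the cycle topology class", {
  g <- elastic_graph(rbind(c(1, 2), c(2, 3), c(3, 4), c(4, 1)), lambda = 0.1)
  pos <- rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1))
  cand <- bisect_edge(g, pos, 2)
  expect_equal(cand$graph$n_nodes, 5L)
  expect_equal(nrow(cand$graph$edges), 5L)
  expect_true(all(node_degrees(cand$graph) == 2L)) # still one cycle
})

test_that("adding a node to a leaf extrapolates the terminal edge", {
  g <- elastic_graph(rbind(c(1, 2), c(2, 3)), lambda = c(0.3, 0.4), mu = 0.2)
  pos <- rbind(c(0, 0), c(0.5, 0), c(1, 0))
  cand <- add_node_to_node(g, pos, 3)
  expect_equal(cand$positions[4, ], c(1.5, 0))
  # new edge copies the terminal edge modulus, new star copies neighbour mu
  e <- cand$graph$edges
  new_e <- which(e[, 1] == 3 & e[, 2] == 4)
  expect_equal(cand$graph$lambdas[new_e], 0.4)
  expect_equal(cand$graph$mus[3], 0.2)
})

test_that("adding a node to a two-node graph assigns the default star modulus", {
  g <- elastic_graph(rbind(c(1, 2)), lambda = 0.1, mu = 0.3)
  pos <- rbind(c(0, 0), c(1, 0))
  cand <- add_node_to_node(g, pos, 2, default_mu = 0.3)
  expect_equal(cand$positions[3, ], c(2, 0))
  expect_equal(cand$graph$mus[2], 0.3)
})

test_that("adding a node to an internal node places it at its points' mean", {
  g <- elastic_graph(rbind(c(1, 2), c(2, 3)), lambda = c(0.2, 0.4), mu = 0.1)
  pos <- rbind(c(-1, 0), c(0, 0), c(1, 0))
  X <- rbind(c(0, 1), c(0, 3))
  part <- partition_data(X, pos)
  cand <- add_node_to_node(g, pos, 2, X, part)
  expect_equal(cand$positions[4, ], c(0, 2))
  new_e <- which(cand$graph$edges[, 1] == 2 & cand$graph$edges[, 2] == 4)
  expect_equal(cand$graph$lambdas[new_e], 0.3) # mean of the star edges
  expect_equal(cand$graph$mus[2], 0.1)         # unchanged
  expect_error(add_node_to_node(g, pos, 9), "no such node")
})

test_that("removing a leaf zeroes the neighbour mu only when it becomes a leaf", {
  g <- elastic_graph(rbind(c(1, 2), c(2, 3)), lambda = 0.1, mu = 0.5)
  pos <- rbind(c(0, 0), c(1, 0), c(2, 0))
  cand <- remove_leaf(g, pos, 3)
  expect_equal(cand$graph$n_nodes, 2L)
  expect_equal(nrow(cand$graph$edges), 1L)
  expect_equal(cand$graph$mus, c(0, 0))
  expect_equal(cand$positions, pos[1:2, ])

  star <- elastic_graph(rbind(c(1, 2), c(1, 3), c(1, 4)), lambda = 0.1,
                        mu = 0.5)
  spos <- rbind(c(0, 0), c(1, 0), c(0, 1), c(-1, 0))
  cand2 <- remove_leaf(star, spos, 4)
  expect_equal(cand2$graph$mus[1], 0.5) # still a 2-star centre
  expect_error(remove_leaf(star, spos, 1), "not a leaf")
})

test_that("shrinking an internal edge merges nodes at the midpoint", {
  g <- elastic_graph(path_edges(4), lambda = 0.1, mu = c(0, 0.2, 0.4, 0))
  pos <- rbind(c(0, 0), c(1, 0), c(2, 0), c(3, 0))
  cand <- shrink_internal_edge(g, pos, 2) # middle edge {2,3}
  expect_equal(cand$graph$n_nodes, 3L)
  expect_equal(nrow(cand$graph$edges), 2L)
  expect_equal(cand$positions[2, ], c(1.5, 0))
  expect_equal(cand$graph$mus[2], 0.3) # average of the two stars
  expect_error(shrink_internal_edge(g, pos, 1), "not internal")
})

test_that("shrinking a triangle edge collapses the duplicate with max modulus", {
  g <- elastic_graph(rbind(c(1, 2), c(2, 3), c(1, 3)),
                     lambda = c(0.1, 0.2, 0.3), mu = 0.1)
  pos <- rbind(c(0, 0), c(1, 0), c(0.5, 1))
  cand <- shrink_internal_edge(g, pos, 1)
  expect_equal(cand$graph$n_nodes, 2L)
  expect_equal(nrow(cand$graph$edges), 1L)
  expect_equal(cand$graph$lambdas, 0.3)
  expect_equal(cand$graph$mus, c(0, 0)) # both endpoints became leaves
})

test_that("candidate enumeration counts match the graph elements", {
  g2 <- elastic_graph(rbind(c(1, 2)), lambda = 0.1)
  pos2 <- rbind(c(0, 0), c(1, 0))
  cands <- generate_candidates(g2, pos2,
                               c("bisect_edge", "add_node_to_node"))
  expect_length(cands, 3L) # 1 bisect + 2 add-node

  set.seed(12)
  n <- 9
  tr <- random_elastic_tree(n)
  posn <- random_positions(n, 2)
  ct <- generate_candidates(tr, posn, c("bisect_edge", "add_node_to_node"),
                            X = posn, partition = partition_data(posn, posn))
  expect_length(ct, nrow(tr$edges) + n)
})

test_that("the reduced search keeps the k longest edges and is a subset", {
  g <- elastic_graph(path_edges(5), lambda = 0.1)
  pos <- matrix(c(0, 1, 3, 6, 10, rep(0, 5)), 5, 2) # lengths 1,2,3,4
  red <- generate_candidates(g, pos, "bisect_edge", max_candidates = 2)
  expect_length(red, 2L)
  mids <- t(vapply(red, function(cc) cc$positions[6, ], numeric(2)))
  expect_setequal(mids[, 1], c((3 + 6) / 2, (6 + 10) / 2))

  full <- generate_candidates(g, pos, "bisect_edge")
  expect_length(full, 4L)
  full_labels <- vapply(full, function(cc) cc$op_label, character(1))
  red_labels <- vapply(red, function(cc) cc$op_label, character(1))
  expect_true(all(red_labels %in% full_labels))
})

test_that("add-node followed by remove-leaf restores topology and moduli", {
  g <- elastic_graph(rbind(c(1, 2), c(2, 3)), lambda = c(0.3, 0.4), mu = 0.2)
  pos <- rbind(c(0, 0), c(0.5, 0), c(1, 0))
  grown <- add_node_to_node(g, pos, 3)
  back <- remove_leaf(grown$graph, grown$positions, 4)
  expect_equal(back$graph$edges, g$edges)
  expect_equal(back$graph$lambdas, g$lambdas)
  expect_equal(back$graph$mus, g$mus)
  expect_equal(back$positions, pos)
})

test_that("every generated candidate is a valid elastic graph", {
  set.seed(13)
  for (rep in 1:10) {
    n <- sample(4:10, 1)
    g <- random_elastic_tree(n)
    pos <- random_positions(n, 2)
    X <- matrix(rnorm(40), 20, 2)
    part <- partition_data(X, pos)
    cands <- generate_candidates(
      g, pos, c("bisect_edge", "add_node_to_node", "remove_leaf",
                "shrink_internal_edge"), X = X, partition = part)
    for (cc in cands) {
      expect_silent(epgraph:::validate_elastic_graph(cc$graph))
      expect_equal(nrow(cc$positions), cc$graph$n_nodes)
    }
  }
})
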