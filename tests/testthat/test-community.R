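test_that("build_network keeps positive cells and records dropped genes", {
  w <- rbind(c(0.5, 0, 0), c(0, 0.7, 0))
  dimnames(w) <- list(c("c1", "c2"), c("p1", "p2", "p3"))
  net <- build_network(w)
  expect_identical(nrow(net$edges), 2L)
  expect_identical(net$dropped_nodes, "p3")
  expect_setequal(net$nodes$node, c("c1", "c2", "p1", "p2"))
  expect_error(build_network(matrix(0, 2, 2,
                                    dimnames = list(c("a", "b"), c("x", "y")))),
               "empty network")
})

test_that("map equation matches hand-evaluated closed forms", {
  net <- two_triangles_net()
  nodes <- net$nodes$node
  # single module: q = 0, L = entropy of uniform visit rates = log2(6)
  s_one <- map_equation(net, setNames(rep(1, 6), nodes))
  expect_equal(s_one$L, log2(6), tolerance = 1e-12)
  expect_equal(s_one$per_module$exit_rate, 0)
  # component partition: p_a = 1/6, q_i = 0, L = 2 * (1/2) * log2(3)
  s_comp <- map_equation(net, setNames(c(1, 1, 1, 2, 2, 2), nodes))
  expect_equal(s_comp$L, log2(3), tolerance = 1e-12)
  expect_lt(s_comp$L, s_one$L)
  # visit rates over modules sum to 1
  expect_equal(sum(s_comp$per_module$visit_rate), 1)
})

test_that("L is invariant to edge-weight scaling and node relabeling", {
  net <- random_small_net(5)
  nodes <- net$nodes$node
  part <- setNames(rep_len(1:2, length(nodes)), nodes)
  L0 <- map_equation(net, part)$L
  scaled <- net
  scaled$edges$weight <- scaled$edges$weight * 2
  expect_equal(map_equation(scaled, part)$L, L0, tolerance = 1e-12)
  # permuting module labels changes nothing
  part2 <- setNames(3 - part, nodes)
  expect_equal(map_equation(net, part2)$L, L0, tolerance = 1e-12)
  expect_error(map_equation(net, part[-1]), "missing")
})

test_that("greedy search matches the exhaustive oracle on small fixtures", {
  fixtures <- c(list(two_triangles_net(), k22_net(), single_edge_net()),
                lapply(1:6, random_small_net))
  for (net in fixtures) {
    ex <- exhaustive_partition_search(net)
    gr <- detect_communities(net, n_restarts = 8, seed = 1)
    expect_lt(abs(gr$score$L - ex$score$L), 1e-12)
    expect_lte(ex$score$L, gr$score$L + 1e-12)
  }
})

test_that("two disjoint triangles resolve into their components", {
  net <- two_triangles_net()
  ex <- exhaustive_partition_search(net)   # B(6) = 203 partitions
  expect_identical(ex$partition$n_modules, 2L)
  expect_equal(ex$score$L, log2(3), tolerance = 1e-12)
  gr <- detect_communities(net, n_restarts = 4, seed = 2)
  expect_identical(sort(table(gr$partition$assignment), decreasing = TRUE),
                   sort(table(ex$partition$assignment), decreasing = TRUE))
})

test_that("complete bipartite 2x2 with equal weights stays one module", {
  ex <- exhaustive_partition_search(k22_net())  # all 15 partitions of 4 nodes
  expect_identical(ex$partition$n_modules, 1L)
  gr <- detect_communities(k22_net(), n_restarts = 4, seed = 1)
  expect_identical(gr$partition$n_modules, 1L)
})

test_that("detection is seeded-deterministic and never beats the baselines", {
  net <- random_small_net(2, nr = 3, nc = 5)
  a <- detect_communities(net, n_restarts = 5, seed = 42)
  b <- detect_communities(net, n_restarts = 5, seed = 42)
  expect_identical(a$partition$assignment, b$partition$assignment)
  expect_identical(a$score$L, b$score$L)
  nodes <- net$nodes$node
  L_one <- map_equation(net, setNames(rep(1, length(nodes)), nodes))$L
  L_sing <- map_equation(net, setNames(seq_along(nodes), nodes))$L
  expect_lte(a$score$L, min(L_one, L_sing) + 1e-12)
})

test_that("planted K = 3 network is recovered with high agreement", {
  pn <- generate_planted_network(15, 90, 3, w_in = 0.6, w_out = 0.05,
                                 edge_prob_in = 0.9, edge_prob_out = 0.1,
                                 seed = 1)
  net <- build_network(pn$matrix)
  d <- detect_communities(net, n_restarts = 10, seed = 1)
  expect_identical(d$partition$n_modules, 3L)
  expect_gte(adjusted_rand_index(d$partition$assignment, pn$truth), 0.9)
})

test_that("modules are named after their highest-degree chaperone", {
  w <- rbind(c(0.9, 0.8, 0), c(0.7, 0, 0), c(0, 0, 0.5))
  dimnames(w) <- list(c("HSPD1", "HSPE1", "SPG7"), c("p1", "p2", "p3"))
  net <- build_network(w)
  part <- structure(list(assignment = setNames(c(1, 1, 2, 1, 1, 2),
                                               c("HSPD1", "HSPE1", "SPG7",
                                                 "p1", "p2", "p3")),
                         n_modules = 2L), class = "partition")
  nm <- name_modules(net, part)
  expect_identical(unname(nm), c("HSPD1", "SPG7"))
})

test_that("network exports are Cytoscape-style TSVs", {
  net <- k22_net()
  d <- detect_communities(net, n_restarts = 2, seed = 1)
  ed <- withr::local_tempfile(fileext = ".tsv")
  nd <- withr::local_tempfile(fileext = ".tsv")
  write_network_tsv(net, d$partition, path_edges = ed, path_nodes = nd)
  edges <- utils::read.delim(ed)
  expect_identical(names(edges), c("source", "target", "weight"))
  nodes <- utils::read.delim(nd)
  expect_identical(names(nodes), c("node", "type", "module", "degree"))
  expect_setequal(nodes$type, c("chaperone", "client"))
})

test_that("the oracle refuses graphs beyond its node limit", {
  pn <- generate_planted_network(4, 8, 2, 0.5, 0.1, 1, 0.5, seed = 1)
  expect_error(exhaustive_partition_search(build_network(pn$matrix)),
               "oracle limit")
})
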