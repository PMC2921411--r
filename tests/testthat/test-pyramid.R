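make_module_set <- function(modules, nodes) {
  ids <- as.character(seq_along(modules))
  names(modules) <- ids
  memb <- stats::setNames(rep(ids, lengths(modules)), unlist(modules))
  structure(list(modules = modules, membership = memb[nodes],
                 s_intra = NULL, s_inter = NULL, isolated = character(0)),
            class = "module_set")
}

test_that("supernode proximity averages member proximities (size-normalized)", {
  nodes <- c("a1", "a2", "b1")
  P <- matrix(0, 3, 3, dimnames = list(nodes, nodes))
  P["a1", "b1"] <- 2; P["a2", "b1"] <- 4
  ms <- make_module_set(list(c("a1", "a2"), "b1"), nodes)
  net <- build_supernode_network(ms, as_pnet(P))
  expect_equal(net$adjacency["1", "2"], 3)          # (2 + 4) / (2 * 1)
  expect_equal(net$adjacency["2", "1"], 0)

  # singleton modules inherit the pair proximity unchanged
  P2 <- matrix(0, 2, 2, dimnames = list(c("a", "b"), c("a", "b")))
  P2["a", "b"] <- 1.7
  ms2 <- make_module_set(list("a", "b"), c("a", "b"))
  net2 <- build_supernode_network(ms2, as_pnet(P2))
  expect_equal(net2$adjacency["1", "2"], 1.7)

  # no cross proximity, no stored link
  P3 <- matrix(0, 2, 2, dimnames = list(c("a", "b"), c("a", "b")))
  ms3 <- make_module_set(list("a", "b"), c("a", "b"))
  expect_equal(n_links(build_supernode_network(ms3, as_pnet(P3))), 0)
})

test_that("a uniform clique collapses to a single module in one stage", {
  K <- matrix(1, 5, 5, dimnames = list(letters[1:5], letters[1:5]))
  diag(K) <- 0
  pyr <- build_pyramid(weighted_network(K, directed = FALSE))
  expect_equal(pyr$n_levels, 1)
  expect_equal(module_counts(pyr), 1L)
  expect_equal(n_nodes(pyr$levels[[1]]$abstract_network), 1)
  expect_false(pyr$stalled)
})

test_that("a single-node network yields one trivial level, not a stall", {
  A <- matrix(0, 1, 1, dimnames = list("x", "x"))
  pyr <- build_pyramid(weighted_network(A, directed = FALSE))
  expect_equal(pyr$n_levels, 1)
  expect_false(pyr$stalled)
  expect_equal(unname(pyr$levels[[1]]$parent_of["x"]), "1")
})

test_that("link-free levels stall with every node its own module", {
  A <- matrix(0, 3, 3, dimnames = list(letters[1:3], letters[1:3]))
  pyr <- build_pyramid(weighted_network(A, directed = FALSE))
  expect_true(pyr$stalled)
  expect_equal(module_counts(pyr)[length(module_counts(pyr))], 3L)
})

test_that("the two-clique network builds the expected two-stage pyramid", {
  pyr <- build_pyramid(two_cliques())
  counts <- module_counts(pyr)
  expect_equal(counts[length(counts)], 2L)           # bottom: the two cliques
  expect_equal(counts[1], 1L)                        # apex: one supernode
  flat <- flatten_membership(pyramid = pyr, level = pyr$n_levels)
  expect_equal(length(unique(flat)), 2)
  expect_equal(unname(flat["a"]), unname(flat["b"]))
  expect_false(unname(flat["a"]) == unname(flat["d"]))
})

test_that("levels conserve nodes, coarsen strictly, and nest vertically", {
  set.seed(5)
  gen <- generate_nested_network(branching = c(3, 3), leaf_size = 5,
                                 target_density = 0.15, rho = 0.3, seed = 9)
  pyr <- build_pyramid(gen$network)
  counts <- vapply(pyr$levels, function(l) length(l$module_set$modules), 0L)
  for (li in seq_len(pyr$n_levels)) {
    lev <- pyr$levels[[li]]
    expect_equal(sum(lengths(lev$module_set$modules)),
                 n_nodes(lev$input_network))
    expect_equal(sort(node_names(lev$abstract_network)),
                 sort(names(lev$module_set$modules)))
    if (!pyr$stalled && n_nodes(lev$input_network) > 1)
      expect_lt(counts[li], n_nodes(lev$input_network))   # strict coarsening
  }
  # vertical nesting: each flattened level refines the one above it
  for (lv in seq_len(pyr$n_levels - 1)) {
    fine <- flatten_membership(pyr, lv + 1)           # deeper level
    coarse <- flatten_membership(pyr, lv)
    expect_true(all(tapply(coarse[names(fine)], fine, function(x)
      length(unique(x)) == 1)))
  }
})

test_that("pyramid construction is deterministic", {
  gen <- generate_nested_network(branching = c(2, 2), leaf_size = 5,
                                 target_density = 0.25, rho = 0.2, seed = 4)
  p1 <- build_pyramid(gen$network, z_threshold = 0)
  p2 <- build_pyramid(gen$network, z_threshold = 0)
  expect_identical(lapply(p1$levels, `[[`, "parent_of"),
                   lapply(p2$levels, `[[`, "parent_of"))
})

test_that("max_levels caps construction and sets the stall flag", {
  gen <- generate_nested_network(branching = c(2, 2), leaf_size = 5,
                                 target_density = 0.25, rho = 0.2, seed = 4)
  pyr <- build_pyramid(gen$network, max_levels = 1)
  expect_equal(pyr$n_levels, 1)
  expect_true(pyr$stalled || length(pyr$levels[[1]]$module_set$modules) == 1)
})

test_that("summary and module_counts report levels top-down", {
  pyr <- build_pyramid(two_cliques())
  s <- summary(pyr)
  expect_equal(nrow(s), pyr$n_levels)
  expect_equal(s$modules[nrow(s)], 2L)               # bottom row
  expect_equal(module_counts(pyr, informative_only = TRUE),
               module_counts(pyr)[module_counts(pyr) > 1])
})
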