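test_that("symmetrization sums the two directions, missing ones as zero", {
  P <- matrix(0, 2, 2, dimnames = list(c("a", "b"), c("a", "b")))
  P["a", "b"] <- 2; P["b", "a"] <- 3
  expect_equal(symmetrize_proximity(as_pnet(P))["a", "b"], 5)
  P["b", "a"] <- 0
  expect_equal(symmetrize_proximity(as_pnet(P))["a", "b"], 2)
  S <- matrix(c(0, 2, 2, 0), 2, dimnames = list(c("a", "b"), c("a", "b")))
  expect_equal(symmetrize_proximity(as_pnet(S, directed = FALSE)), S * 2)
})

test_that("the spanning forest picks the maximum-weight tree per component", {
  W <- matrix(0, 3, 3, dimnames = list(LETTERS[1:3], LETTERS[1:3]))
  W["A", "B"] <- W["B", "A"] <- 3
  W["B", "C"] <- W["C", "B"] <- 2
  W["A", "C"] <- W["C", "A"] <- 1
  bb <- maximum_spanning_forest(W)
  expect_equal(sum(bb$edges$weight), 5)
  expect_setequal(paste(bb$edges$from, bb$edges$to),
                  c("A B", "B C"))

  # an input that is already a tree is its own backbone
  Tm <- matrix(0, 4, 4, dimnames = list(letters[1:4], letters[1:4]))
  Tm["a", "b"] <- Tm["b", "a"] <- 1
  Tm["b", "c"] <- Tm["c", "b"] <- 2
  Tm["c", "d"] <- Tm["d", "c"] <- 3
  bbT <- maximum_spanning_forest(Tm)
  expect_equal(nrow(bbT$edges), 3)
  expect_equal(sum(bbT$edges$weight), 6)

  # disjoint components give one tree each; isolated nodes their own tree
  D <- matrix(0, 5, 5, dimnames = list(letters[1:5], letters[1:5]))
  D["a", "b"] <- D["b", "a"] <- 1
  D["c", "d"] <- D["d", "c"] <- 1
  bbD <- maximum_spanning_forest(D)
  expect_equal(bbD$n_trees, 3)
  expect_equal(as.integer(sort(table(bbD$tree_id))), c(1L, 2L, 2L))
})

test_that("forest weight equals the exhaustive-search optimum on random graphs", {
  set.seed(19)
  for (rep in 1:200) {
    n <- sample(3:7, 1)
    nodes <- paste0("v", seq_len(n))
    A <- matrix(0, n, n, dimnames = list(nodes, nodes))
    ut <- which(upper.tri(A))
    picked <- ut[stats::runif(length(ut)) < 0.55]
    A[picked] <- stats::runif(length(picked), 0.1, 5)
    A <- A + t(A)
    bb <- maximum_spanning_forest(A)
    expect_equal(sum(bb$edges$weight), brute_msf_weight(A), tolerance = 1e-9)
  }
})

test_that("forest weight agrees with igraph's spanning tree on larger graphs", {
  skip_if_not_installed("igraph")
  set.seed(23)
  for (rep in 1:20) {
    net <- rand_network(15, 0.3, weighted = TRUE)
    A <- net$adjacency
    bb <- maximum_spanning_forest(A)
    g <- igraph::graph_from_adjacency_matrix(A, mode = "undirected",
                                             weighted = TRUE)
    m <- igraph::mst(g, weights = -igraph::E(g)$weight)
    expect_equal(sum(bb$edges$weight), sum(igraph::E(m)$weight),
                 tolerance = 1e-9)
  }
})

test_that("ties break deterministically and runs repeat bit-for-bit", {
  W <- matrix(0, 4, 4, dimnames = list(letters[1:4], letters[1:4]))
  W[upper.tri(W)] <- 1
  W <- W + t(W)
  b1 <- maximum_spanning_forest(W)
  b2 <- maximum_spanning_forest(W)
  expect_identical(b1$edges, b2$edges)
  expect_equal(nrow(b1$edges), 3)
})

test_that("two cliques joined by a weak bridge split into exactly the cliques", {
  net <- two_cliques()
  pn <- zscore_filter(compute_proximity(net), -10)
  bb <- maximum_spanning_forest(symmetrize_proximity(pn))
  ms <- partition_backbone(bb, pn)
  expect_length(ms$modules, 2)
  expect_setequal(vapply(ms$modules, function(m) paste(sort(m), collapse = ""),
                         ""), c("abc", "def"))
  expect_true(criterion_holds(ms, pn))
})

test_that("a uniform star refuses every split and stays one module", {
  nodes <- c("h", paste0("l", 1:4))
  A <- matrix(0, 5, 5, dimnames = list(nodes, nodes))
  A["h", -1] <- 1; A[-1, "h"] <- 1
  net <- weighted_network(A, directed = FALSE)
  pn <- zscore_filter(compute_proximity(net), -10)
  bb <- maximum_spanning_forest(symmetrize_proximity(pn))
  ms <- partition_backbone(bb, pn)
  expect_length(ms$modules, 1)
})

test_that("a single node is a singleton module", {
  A <- matrix(0, 1, 1, dimnames = list("x", "x"))
  pn <- as_pnet(A)
  bb <- maximum_spanning_forest(A)
  ms <- partition_backbone(bb, pn)
  expect_length(ms$modules, 1)
  expect_equal(ms$modules[[1]], "x")
})

test_that("partitions conserve nodes and satisfy the criterion on random fixtures", {
  set.seed(31)
  for (rep in 1:15) {
    net <- rand_network(sample(6:14, 1), 0.35, weighted = TRUE)
    pn <- compute_proximity(net)
    if (!any(pn$prox > 0)) next
    pf <- zscore_filter(pn, 0)
    bb <- maximum_spanning_forest(symmetrize_proximity(pf))
    ms <- partition_backbone(bb, pf)
    expect_setequal(unlist(ms$modules, use.names = FALSE),
                    rownames(pf$prox))
    expect_true(criterion_holds(ms, pf))
  }
})

test_that("isolated nodes surface as flagged singleton modules", {
  A <- matrix(0, 4, 4, dimnames = list(letters[1:4], letters[1:4]))
  A["a", "b"] <- A["b", "a"] <- 2
  net <- weighted_network(A, directed = FALSE)
  pn <- zscore_filter(compute_proximity(net), -5)
  bb <- maximum_spanning_forest(symmetrize_proximity(pn))
  ms <- partition_backbone(bb, pn)
  iso_members <- unlist(ms$modules[ms$isolated], use.names = FALSE)
  expect_setequal(iso_members, c("c", "d"))
})
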