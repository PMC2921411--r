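test_that("edge lists read back with weights, defaults and both directions", {
  f <- withr::local_tempfile(lines = c("# comment", "a b 2", "b c 3", ""))
  net <- read_edge_list(f, directed = FALSE)
  expect_setequal(rownames(net$adjacency), c("a", "b", "c"))
  expect_equal(net$adjacency["a", "b"], 2)
  expect_equal(net$adjacency["b", "a"], 2)
  expect_equal(net$adjacency["b", "c"], 3)
  expect_equal(n_links(net), 2)

  f2 <- withr::local_tempfile(lines = "a b")
  net2 <- read_edge_list(f2, default_weight = 1)
  expect_equal(net2$adjacency["a", "b"], 1)
  net25 <- read_edge_list(f2, default_weight = 2.5)
  expect_equal(net25$adjacency["a", "b"], 2.5)
})

test_that("self-links are dropped and duplicates merged by summation, with warnings", {
  f <- withr::local_tempfile(lines = c("a a 5", "b c 1"))
  expect_warning(net <- read_edge_list(f), "self-link")
  expect_equal(n_links(net), 1)
  expect_false("a" %in% rownames(net$adjacency) && net$adjacency["a", "a"] != 0)

  f2 <- withr::local_tempfile(lines = c("a b 2", "b a 3"))
  expect_warning(net2 <- read_edge_list(f2, directed = FALSE), "duplicate")
  expect_equal(net2$adjacency["a", "b"], 5)
  net2d <- read_edge_list(f2, directed = TRUE)   # distinct directions, no merge
  expect_equal(net2d$adjacency["a", "b"], 2)
  expect_equal(net2d$adjacency["b", "a"], 3)
})

test_that("malformed records fail with the offending line number", {
  f <- withr::local_tempfile(lines = c("a b 1", "oops", "c d 1"))
  expect_error(read_edge_list(f), "line 2")
  f2 <- withr::local_tempfile(lines = c("a b -1"))
  expect_error(read_edge_list(f2), "negative")
  f3 <- withr::local_tempfile(lines = c("a b x"))
  expect_error(read_edge_list(f3), "non-numeric")
})

test_that("write/read round-trips reproduce networks up to node order", {
  set.seed(41)
  for (directed in c(FALSE, TRUE)) {
    net <- rand_network(8, 0.4, directed = directed, weighted = TRUE)
    f <- withr::local_tempfile()
    write_edge_list(net, f)
    back <- read_edge_list(f, directed = directed)
    nodes <- intersect(rownames(net$adjacency), rownames(back$adjacency))
    connected <- rowSums(net$adjacency) + colSums(net$adjacency) > 0
    expect_setequal(rownames(back$adjacency),
                    rownames(net$adjacency)[connected])
    expect_equal(back$adjacency[nodes, nodes], net$adjacency[nodes, nodes])
  }
})

test_that("stored link count equals well-formed non-self input records", {
  f <- withr::local_tempfile(lines = c("a b 1", "b c 2", "c a 1", "d d 9"))
  expect_warning(net <- read_edge_list(f), "self-link")
  expect_equal(n_links(net), 3)
})

test_that("a trivial single-node pyramid writes three files and one membership row", {
  A <- matrix(0, 1, 1, dimnames = list("x", "x"))
  pyr <- build_pyramid(weighted_network(A, directed = FALSE))
  d <- withr::local_tempdir()
  files <- write_pyramid(pyr, d)
  expect_length(files, 3)
  memb <- read.delim(file.path(d, "membership_level1.tsv"))
  expect_equal(nrow(memb), 1)
})

test_that("the two-clique pyramid writes a 6-row, 2-module bottom membership", {
  pyr <- build_pyramid(two_cliques())
  d <- withr::local_tempdir()
  write_pyramid(pyr, d)
  bottom <- read.delim(file.path(d, sprintf("membership_level%d.tsv", pyr$n_levels)))
  expect_equal(nrow(bottom), 6)
  expect_equal(length(unique(bottom$module_id)), 2)
})

test_that("pyramids survive a write/read round-trip structurally intact", {
  pyr <- build_pyramid(two_cliques(), z_threshold = 0, seed = 7)
  d <- withr::local_tempdir()
  write_pyramid(pyr, d)
  back <- read_pyramid(d)
  expect_equal(back$n_levels, pyr$n_levels)
  expect_equal(back$stalled, pyr$stalled)
  expect_equal(back$params$z_threshold, pyr$params$z_threshold)
  expect_equal(back$params$seed, pyr$params$seed)
  for (lv in seq_len(pyr$n_levels)) {
    expect_equal(back$levels[[lv]]$parent_of, pyr$levels[[lv]]$parent_of)
    expect_equal(back$levels[[lv]]$abstract_network$adjacency,
                 pyr$levels[[lv]]$abstract_network$adjacency, tolerance = 1e-9)
    expect_equal(sort(names(back$levels[[lv]]$module_set$modules)),
                 sort(names(pyr$levels[[lv]]$module_set$modules)))
  }
  expect_equal(back$levels[[1]]$input_network$adjacency,
               pyr$levels[[1]]$input_network$adjacency, tolerance = 1e-9)
})

test_that("annotation tables read from TSV with or without a header", {
  f <- withr::local_tempfile(lines = c("node_id\tcategory_id", "a\tC1", "b\tC1", "c\tC2"))
  ann <- read_annotations(f)
  expect_setequal(ann$background, c("a", "b", "c"))
  expect_equal(ann$membership[["a"]], "C1")
  f2 <- withr::local_tempfile(lines = c("a\tC1", "b\tC2"))
  ann2 <- read_annotations(f2)
  expect_length(ann2$membership, 2)
})
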