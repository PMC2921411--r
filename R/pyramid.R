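#' Collapse modules into a supernode network
#'
#' Treats each module as a supernode and defines the proximity between two
#' supernodes as the size-normalized sum of the node proximities between
#' their members:
#' \deqn{prox_{super}(M_a, M_b) = \frac{1}{|M_a| |M_b|}
#'   \sum_{m \in M_a, n \in M_b} prox(m, n)}
#' The un-thresholded proximities of the current level are averaged, so
#' module pairs connected only through below-threshold links are not
#' silently zeroed; thresholding is re-applied when the next level's
#' proximity is standardized. Zero-weight pairs are not stored. The result
#' is the next level's input network.
#'
#' @param module_set A [partition_backbone()] result.
#' @param pnet The un-thresholded `proximity_network` of the current level.
#' @return A [weighted_network()] whose nodes are the module ids.
#' @export
build_supernode_network <- function(module_set, pnet) {
  stopifnot(inherits(module_set, "module_set"), inherits(pnet, "proximity_network"))
  P <- pnet$prox
  nodes <- names(module_set$membership)
  if (!setequal(nodes, rownames(P)))
    stop("module set must partition the proximity network's node set")
  P <- P[nodes, nodes, drop = FALSE]
  memb <- factor(module_set$membership,
                 levels = names(module_set$modules))
  M1 <- rowsum(P, memb, reorder = FALSE)
  G <- t(rowsum(t(M1), memb, reorder = FALSE))
  sz <- lengths(module_set$modules)
  W <- G / outer(sz, sz)
  diag(W) <- 0
  dimnames(W) <- list(names(module_set$modules), names(module_set$modules))
  # the proximity measure weighs the two directions of a pair by each
  # endpoint's outgoing strength, so the supernode matrix is asymmetric in
  # general even for undirected input; keep it directed unless it is
  # (numerically) symmetric
  if (isTRUE(all.equal(W, t(W), check.attributes = FALSE))) {
    W <- (W + t(W)) / 2
    weighted_network(W, directed = FALSE)
  } else {
    weighted_network(W, directed = TRUE)
  }
}

#' Build an abstraction pyramid from a weighted network
#'
#' The package's main entry point. Starting from the input network, each
#' iteration (one pyramid level) computes the node proximity, prunes weak
#' links by z-score, extracts the maximum-spanning-forest backbone,
#' partitions the level's network into modules along the backbone, and
#' collapses the modules into a supernode network that becomes the next
#' level's input. Iteration stops when the supernode network has a single
#' node (a complete pyramid), when no coarsening happened (as many modules
#' as nodes; the pyramid is returned with `stalled = TRUE`), or at
#' `max_levels`.
#'
#' Levels are numbered as in the printed hierarchy: level 1 is the top
#' (coarsest) level, the bottom level has the largest number. Internally the
#' pyramid is built bottom-up.
#'
#' @param net A [weighted_network()] (or a square named adjacency matrix,
#'   coerced via [weighted_network()] as undirected unless asymmetric).
#' @param z_threshold Z-score threshold for link pruning at every level
#'   (default 0; see [zscore_filter()]).
#' @param max_levels Safety bound on the number of levels (default 50).
#' @param seed Optional integer recorded in the pyramid's parameters (the
#'   construction itself is deterministic; the seed documents the provenance
#'   of generated inputs).
#' @return An object of class `pyramid`: a list with `levels` (bottom-up
#'   list; each level holds `input_network`, `module_set`,
#'   `abstract_network`, `parent_of`), `params`, `stalled`, and `n_levels`.
#' @seealso [summary.pyramid()], [flatten_membership()], [write_pyramid()]
#' @examples
#' A <- matrix(0, 6, 6, dimnames = list(letters[1:6], letters[1:6]))
#' A[cbind(c(1, 2, 1, 4, 5, 4, 3), c(2, 3, 3, 5, 6, 6, 4))] <- c(rep(5, 6), 1)
#' net <- weighted_network(A + t(A), directed = FALSE)
#' pyr <- build_pyramid(net)
#' summary(pyr)
#' @export
build_pyramid <- function(net, z_threshold = 0, max_levels = 50, seed = NULL) {
  if (is.matrix(net)) {
    directed <- !isTRUE(all.equal(net, t(net), check.attributes = FALSE))
    net <- weighted_network(net, directed = directed)
  }
  stopifnot(inherits(net, "weighted_network"))
  if (n_nodes(net) < 1) stop("network must have at least one node")
  if (!is.finite(z_threshold)) stop("'z_threshold' must be finite")
  if (max_levels < 1) stop("'max_levels' must be at least 1")

  params <- list(z_threshold = z_threshold, directed = net$directed,
                 max_levels = max_levels, seed = seed)
  levels <- list()
  current <- net
  stalled <- FALSE
  repeat {
    n <- n_nodes(current)
    pnet <- compute_proximity(current)
    if (n == 1L || !any(pnet$prox > 0)) {
      # single node, or a link-free level: every node is its own module
      ids <- as.character(seq_len(n))
      modules <- stats::setNames(as.list(node_names(current)), ids)
      ms <- structure(list(
        modules = modules,
        membership = stats::setNames(ids, node_names(current)),
        s_intra = stats::setNames(numeric(n), ids),
        s_inter = matrix(0, n, n, dimnames = list(ids, ids)),
        isolated = if (n > 1L) ids else character(0)), class = "module_set")
      abs_net <- build_supernode_network(ms, pnet)
      levels[[length(levels) + 1L]] <- list(input_network = current,
                                            module_set = ms,
                                            abstract_network = abs_net,
                                            parent_of = ms$membership)
      stalled <- n > 1L
      break
    }
    pfilt <- zscore_filter(pnet, z_threshold)
    bb <- maximum_spanning_forest(symmetrize_proximity(pfilt))
    ms <- partition_backbone(bb, pfilt)
    abs_net <- build_supernode_network(ms, pnet)
    levels[[length(levels) + 1L]] <- list(input_network = current,
                                          module_set = ms,
                                          abstract_network = abs_net,
                                          parent_of = ms$membership)
    n_mod <- length(ms$modules)
    if (n_mod == 1L) break
    if (n_mod == n) { stalled <- TRUE; break }
    if (length(levels) >= max_levels) { stalled <- TRUE; break }
    current <- abs_net
  }
  structure(list(levels = levels, params = params, stalled = stalled,
                 n_levels = length(levels)),
            class = "pyramid")
}

#' @export
print.pyramid <- function(x, ...) {
  counts <- vapply(x$levels, function(l) length(l$module_set$modules), 0L)
  cat(sprintf("Abstraction pyramid: %d level(s)%s\n", x$n_levels,
              if (x$stalled) " [stalled before reaching a single supernode]" else ""))
  cat("  modules per level (top -> bottom): ",
      paste(rev(counts), collapse = ", "), "\n", sep = "")
  cat(sprintf("  z-threshold %g, %s input\n", x$params$z_threshold,
              if (x$params$directed) "directed" else "undirected"))
  invisible(x)
}

#' Summarize an abstraction pyramid
#'
#' @param object A [build_pyramid()] result.
#' @param ... Unused.
#' @return A data.frame with one row per level in printed order (level 1 =
#'   top): number of nodes and links of the level's input network, number of
#'   modules, mean module size, and count of isolated singleton modules.
#' @export
summary.pyramid <- function(object, ...) {
  rows <- lapply(object$levels, function(l) {
    data.frame(nodes = n_nodes(l$input_network),
               links = n_links(l$input_network),
               modules = length(l$module_set$modules),
               mean_module_size = mean(lengths(l$module_set$modules)),
               isolated = length(l$module_set$isolated))
  })
  out <- do.call(rbind, rev(rows))
  out <- cbind(level = seq_len(nrow(out)), out)
  rownames(out) <- NULL
  class(out) <- c("summary.pyramid", "data.frame")
  out
}

#' @export
print.summary.pyramid <- function(x, ...) {
  cat("Abstraction pyramid (level 1 = top):\n")
  print.data.frame(x, row.names = FALSE)
  invisible(x)
}

#' Plot module counts across pyramid levels
#'
#' A base-graphics profile of the pyramid: module count per level on a log
#' scale, top level at the left.
#'
#' @param x A [build_pyramid()] result.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.pyramid <- function(x, ...) {
  counts <- rev(vapply(x$levels, function(l) length(l$module_set$modules), 0L))
  graphics::plot(seq_along(counts), counts, type = "b", log = "y",
                 xlab = "level (1 = top)", ylab = "modules",
                 main = "Abstraction pyramid profile", ...)
  invisible(x)
}

#' Flatten a pyramid level to a partition of the original nodes
#'
#' Composes the child-to-parent maps from the bottom level up, assigning
#' every original (bottom-level) node its module id at the requested level.
#'
#' @param pyramid A [build_pyramid()] result.
#' @param level Level number in printed order (1 = top) by default.
#' @param from_top Logical; set `FALSE` to count levels from the bottom
#'   (1 = bottom) instead.
#' @return A named character vector mapping each original node to a module
#'   id of the requested level.
#' @export
flatten_membership <- function(pyramid, level, from_top = TRUE) {
  stopifnot(inherits(pyramid, "pyramid"))
  k <- pyramid$n_levels
  li <- if (from_top) k - level + 1L else level
  if (li < 1L || li > k) stop("level out of range")
  memb <- pyramid$levels[[1L]]$parent_of
  if (li >= 2L) for (j in 2:li) memb <- stats::setNames(
    pyramid$levels[[j]]$parent_of[memb], names(memb))
  memb
}

#' Module counts per level, top-down
#'
#' @param pyramid A [build_pyramid()] result.
#' @param informative_only Drop levels with a single module (the trivial
#'   apex) when `TRUE`.
#' @return Integer vector of module counts from the top level down.
#' @export
module_counts <- function(pyramid, informative_only = FALSE) {
  counts <- rev(vapply(pyramid$levels, function(l) length(l$module_set$modules), 0L))
  if (informative_only) counts <- counts[counts > 1L]
  counts
}
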