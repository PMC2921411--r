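#' Tier edge probabilities for the nested random-network generator
#'
#' Edge probabilities for hierarchically nested random networks depend on
#' the hierarchical distance `d` between two nodes: `d = 0` for nodes
#' sharing a bottom module, up to `d = D` (the hierarchy depth) for nodes
#' sharing no module. The tier law is geometric, `p_d = c * rho^d`, with the
#' cohesion parameter `rho` in (0, 1): the smaller `rho`, the more cohesive
#' the planted levels. The constant `c` is calibrated in closed form so that
#' the expected number of edges matches `target_density * n * (n - 1) / 2`.
#'
#' At the defaults (640 nodes, branching 4/4/4, leaf size 10, density
#' 0.0225, rho 0.25) each node has 9, 30, 120, and 480 potential partners at
#' distances 0..3, giving `p_0 = 0.0225 * 639 / 31.5` (about 0.456).
#'
#' @param branching Integer vector, modules per parent from the top level
#'   down (default `c(4, 4, 4)`).
#' @param leaf_size Nodes per bottom module (default 10).
#' @param target_density Desired expected edge density (default 0.0225).
#' @param rho Cohesion parameter in (0, 1); default 0.25.
#' @return Numeric vector `p_0 .. p_D` of tier probabilities.
#' @export
calibrate_probabilities <- function(branching = c(4, 4, 4), leaf_size = 10,
                                    target_density = 0.0225, rho = 0.25) {
  if (any(branching < 2) || leaf_size < 2)
    stop("'branching' entries and 'leaf_size' must be at least 2")
  if (rho <= 0 || rho >= 1) stop("'rho' must be in (0, 1)")
  if (target_density <= 0 || target_density > 1)
    stop("'target_density' must be in (0, 1]")
  D <- length(branching)
  sizes <- leaf_size * cumprod(c(1, rev(branching)))  # nested module sizes, bottom-up
  n <- sizes[D + 1]
  partners <- c(leaf_size - 1, diff(sizes))           # partner count per tier d = 0..D
  cc <- target_density * (n - 1) / sum(partners * rho^(0:D))
  p <- cc * rho^(0:D)
  if (p[1] > 1)
    stop("calibration requires p_0 > 1; increase 'rho' or lower 'target_density'")
  names(p) <- paste0("d", 0:D)
  p
}

#' Generate a hierarchically nested random network
#'
#' Samples an undirected unit-weight network with a planted nested module
#' structure: nodes are assigned to equally sized modules at every level of
#' a balanced hierarchy, and each unordered node pair receives an edge
#' independently with the tier probability of its hierarchical distance
#' (see [calibrate_probabilities()]). The defaults reproduce the standard
#' three-level benchmark: 640 nodes in 4 top modules of 160, each split into
#' 4 modules of 40, each split into 4 bottom modules of 10, at overall
#' density 0.0225.
#'
#' @inheritParams calibrate_probabilities
#' @param seed Optional integer seed; the same seed reproduces the exact
#'   edge set.
#' @return A list with `network` (a [weighted_network()]), `truth` (a
#'   `nested_partition`: list of planted membership vectors, top level
#'   first), and `probabilities` (the tier probabilities used).
#' @export
generate_nested_network <- function(branching = c(4, 4, 4), leaf_size = 10,
                                    target_density = 0.0225, rho = 0.25,
                                    seed = NULL) {
  p <- calibrate_probabilities(branching, leaf_size, target_density, rho)
  D <- length(branching)
  n <- leaf_size * prod(branching)
  nodes <- sprintf("n%0*d", nchar(n), seq_len(n))

  # planted membership at each level, top first; nodes are block-assigned
  sizes_top_down <- n / cumprod(branching)   # module size per level, top first
  truth_levels <- lapply(sizes_top_down, function(s) {
    stats::setNames(as.character((seq_len(n) - 1L) %/% s + 1L), nodes)
  })
  truth <- structure(list(levels = truth_levels, branching = branching,
                          leaf_size = leaf_size, nodes = nodes),
                     class = "nested_partition")

  # hierarchical distance = depth minus number of shared levels
  shared <- matrix(0L, n, n)
  for (lv in truth_levels) shared <- shared + outer(lv, lv, `==`)
  dmat <- D - shared

  if (!is.null(seed)) set.seed(seed)
  U <- matrix(0, n, n)
  ut <- upper.tri(U)
  U[ut] <- stats::runif(sum(ut))
  A <- matrix(0, n, n, dimnames = list(nodes, nodes))
  A[ut][U[ut] < p[dmat[ut] + 1L]] <- 1
  A <- A + t(A)
  list(network = weighted_network(A, directed = FALSE), truth = truth,
       probabilities = p)
}

#' @export
print.nested_partition <- function(x, ...) {
  counts <- vapply(x$levels, function(lv) length(unique(lv)), 0L)
  cat(sprintf("Nested planted partition: %d nodes, %d level(s) with %s modules\n",
              length(x$nodes), length(x$levels), paste(counts, collapse = ", ")))
  invisible(x)
}

#' Thin a network to a lower density by random link removal
#'
#' Removes uniformly random links without replacement until exactly
#' `floor(target_density * n * (n - 1) / 2)` unordered links remain, so
#' density sweeps are noiseless in link count.
#'
#' @param net An undirected [weighted_network()].
#' @param target_density Desired density, at most the current density.
#' @param seed Optional integer seed for the removal draw.
#' @return The thinned [weighted_network()].
#' @export
thin_to_density <- function(net, target_density, seed = NULL) {
  stopifnot(inherits(net, "weighted_network"))
  if (net$directed) stop("thinning is defined for undirected networks")
  n <- n_nodes(net)
  target <- floor(target_density * n * (n - 1) / 2)
  idx <- which(net$adjacency > 0 & upper.tri(net$adjacency))
  if (target > length(idx))
    stop("'target_density' exceeds the current density")
  if (!is.null(seed)) set.seed(seed)
  keep <- if (target > 0) sample(idx, target) else integer(0)
  A <- matrix(0, n, n, dimnames = dimnames(net$adjacency))
  A[keep] <- net$adjacency[keep]
  A <- A + t(A)
  weighted_network(A, directed = FALSE)
}
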