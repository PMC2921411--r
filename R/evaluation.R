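#' Normalized mutual information between two partitions
#'
#' Information-theoretic agreement between two flat partitions of the same
#' node universe: `NMI = 2 I(P;Q) / (H(P) + H(Q))` with natural-log
#' entropies over the joint label-count contingency table. Identical
#' partitions (up to label permutation) score 1; independent ones score 0.
#' Conventions for degenerate cases: if both entropies are zero (both
#' partitions all-in-one) the partitions are identical and the score is 1;
#' if exactly one entropy is zero the score is 0.
#'
#' @param p,q Named vectors of cluster labels over the same node set
#'   (names are node ids; values are labels, compared as factors).
#' @return A single number in `[0, 1]`.
#' @export
normalized_mutual_information <- function(p, q) {
  if (is.null(names(p)) || is.null(names(q)))
    stop("'p' and 'q' must be named label vectors")
  if (!setequal(names(p), names(q)))
    stop("'p' and 'q' must label the same node universe")
  q <- q[names(p)]
  tab <- table(as.character(p), as.character(q))
  N <- sum(tab)
  pr <- rowSums(tab) / N
  pc <- colSums(tab) / N
  Hp <- -sum(pr[pr > 0] * log(pr[pr > 0]))
  Hq <- -sum(pc[pc > 0] * log(pc[pc > 0]))
  if (Hp == 0 && Hq == 0) return(1)
  if (Hp == 0 || Hq == 0) return(0)
  pj <- tab / N
  nz <- pj > 0
  I <- sum(pj[nz] * log(pj[nz] / (pr[row(pj)[nz]] * pc[col(pj)[nz]])))
  max(0, min(1, 2 * I / (Hp + Hq)))
}

#' Score a recovered pyramid against a planted nested partition
#'
#' Matches each planted truth level to a recovered pyramid level and
#' computes the normalized mutual information between the flattened
#' recovered partition and the planted one at each matched level.
#' Single-module pyramid levels (the trivial apex) carry no partition
#' information and are dropped before matching. Both hierarchies are
#' anchored at the original nodes, so levels are aligned by depth from the
#' bottom: the finest recovered level scores against the finest planted
#' level, and so on upward. A recovered pyramid may legitimately contain
#' additional coarse levels above the planted root scale; these are
#' ignored. If the pyramid has fewer informative levels than the truth,
#' unmatched truth levels score against the closest available level and
#' are flagged.
#'
#' @param pyramid A [build_pyramid()] result whose bottom-level nodes are
#'   the planted nodes.
#' @param truth A `nested_partition` (see [generate_nested_network()]).
#' @return A data.frame with one row per truth level (top first): the truth
#'   and matched module counts, the per-level NMI, and a `flagged` column
#'   marking levels scored against a substituted pyramid level. The mean
#'   NMI is attached as attribute `mean_nmi`.
#' @export
evaluate_hierarchy <- function(pyramid, truth) {
  stopifnot(inherits(pyramid, "pyramid"), inherits(truth, "nested_partition"))
  orig <- node_names(pyramid$levels[[1L]]$input_network)
  if (!setequal(orig, truth$nodes))
    stop("pyramid and planted truth must cover the same nodes")
  k <- pyramid$n_levels
  flat <- lapply(seq_len(k), function(lv) flatten_membership(pyramid, lv))  # top-down
  counts <- vapply(flat, function(f) length(unique(f)), 0L)
  informative <- which(counts > 1L)
  n_t <- length(truth$levels)
  offset <- length(informative) - n_t   # >0: extra coarse levels, ignored
  rows <- lapply(seq_len(n_t), function(t) {
    if (length(informative) == 0) {
      pred_idx <- k; flag <- TRUE
    } else if (t + offset >= 1) {
      pred_idx <- informative[t + offset]; flag <- FALSE
    } else {
      pred_idx <- informative[1]; flag <- TRUE
    }
    data.frame(truth_level = t,
               truth_modules = length(unique(truth$levels[[t]])),
               pred_modules = counts[pred_idx],
               nmi = normalized_mutual_information(flat[[pred_idx]],
                                                   truth$levels[[t]]),
               flagged = flag)
  })
  out <- do.call(rbind, rows)
  attr(out, "mean_nmi") <- mean(out$nmi)
  out
}
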