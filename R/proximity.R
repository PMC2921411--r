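#' Node proximity from network topology
#'
#' Computes the directed proximity `prox(i, j)` between every ordered node
#' pair of a weighted network. The measure combines the direct link weight
#' with probability-weighted contributions from two-step paths through
#' common neighbours:
#'
#' \deqn{prox(i,j) = A_{ij} + \sum_{k: A_{ik}>0, A_{kj}>0}
#'   \frac{A_{ik}}{W_i^{out} - A_{ij}} \cdot \frac{A_{kj}}{W_k^{out}}
#'   \cdot \min(A_{ik}, A_{kj})}
#'
#' where \eqn{W_i^{out} = \sum_m A_{im}} is the total outgoing weight of
#' node `i`. The first factor is the probability that `i` affects `k` given
#' that it does not use the direct link to `j`; the second is the probability
#' that `k` affects `j`; the `min` term scales the indirect contribution by
#' the weaker of the two link weights. Pairs with neither a direct link nor a
#' common neighbour have proximity zero and are not stored.
#'
#' @param net A [weighted_network()]. For undirected networks the symmetric
#'   adjacency makes the proximity symmetric as well.
#' @return An object of class `proximity_network`: a list with elements
#'   `prox` (dense matrix, zero for unstored pairs), `directed`,
#'   `zscores` (`NULL` until [zscore_filter()] is applied) and
#'   `threshold_applied` (`NULL` or the z-score threshold used).
#' @seealso [zscore_filter()], [symmetrize_proximity()]
#' @export
compute_proximity <- function(net) {
  stopifnot(inherits(net, "weighted_network"))
  A <- net$adjacency
  n <- nrow(A)
  if (n < 1) stop("network must have at least one node")
  W <- rowSums(A)
  Wk <- ifelse(W > 0, W, 1)  # rows with no outgoing links contribute nothing
  P <- matrix(0, n, n, dimnames = dimnames(A))
  for (i in seq_len(n)) {
    if (W[i] == 0) next
    ks <- which(A[i, ] > 0)
    a <- A[i, ks]
    # S[j] = sum_k A_ik * (A_kj / W_k) * min(A_ik, A_kj); rows of M are the
    # out-rows of the neighbours k, so length-|ks| vectors recycle per row.
    M <- A[ks, , drop = FALSE]
    S <- colSums((a / Wk[ks]) * M * pmin(M, a))
    denom <- W[i] - A[i, ]
    denom[denom <= 0] <- Inf  # only reachable when the indirect sum is empty
    P[i, ] <- A[i, ] + S / denom
  }
  diag(P) <- 0
  structure(list(prox = P, directed = net$directed,
                 zscores = NULL, threshold_applied = NULL),
            class = "proximity_network")
}

#' @export
print.proximity_network <- function(x, ...) {
  cat(sprintf("Proximity network: %d nodes, %d stored pairs%s\n",
              nrow(x$prox), sum(x$prox > 0),
              if (is.null(x$threshold_applied)) ""
              else sprintf(" (z-filtered at %g)", x$threshold_applied)))
  invisible(x)
}

#' Prune weak proximities by z-score
#'
#' Standardizes all stored (non-zero) proximity values of the current level
#' with their population mean and population standard deviation, and keeps
#' exactly the pairs whose z-score is at or above `threshold`. For directed
#' networks both directions pool into one population. Discarding the
#' below-threshold links reduces the search space for the backbone and the
#' partition; the default threshold 0 keeps the above-average half.
#'
#' @param pnet A `proximity_network` from [compute_proximity()].
#' @param threshold Z-score cut-off; links with `(prox - mu) / sigma <
#'   threshold` are discarded. If the population standard deviation is zero,
#'   all links are kept.
#' @return A `proximity_network` with the surviving pairs, their z-scores in
#'   `zscores`, and `threshold_applied` set.
#' @export
zscore_filter <- function(pnet, threshold = 0) {
  stopifnot(inherits(pnet, "proximity_network"))
  if (!is.finite(threshold)) stop("'threshold' must be finite")
  P <- pnet$prox
  stored <- P > 0
  if (!any(stored)) stop("proximity network has no stored pairs")
  v <- P[stored]
  mu <- mean(v)
  sigma <- sqrt(mean((v - mu)^2))  # population SD
  Z <- matrix(NA_real_, nrow(P), ncol(P), dimnames = dimnames(P))
  if (sigma == 0) {
    Z[stored] <- 0
    keep <- stored
  } else {
    Z[stored] <- (v - mu) / sigma
    keep <- stored & !is.na(Z) & Z >= threshold
  }
  Pk <- P
  Pk[!keep] <- 0
  Z[!keep] <- NA_real_
  structure(list(prox = Pk, directed = pnet$directed,
                 zscores = Z, threshold_applied = threshold),
            class = "proximity_network")
}

#' Symmetrize a proximity network for backbone extraction
#'
#' Spanning trees are undirected objects, so the two directed proximities of
#' each unordered pair are summed into a single weight:
#' `w(i, j) = prox(i, j) + prox(j, i)`, a missing direction counting as 0.
#' Reciprocated pairs therefore rank higher than one-way ones.
#'
#' @param pnet A `proximity_network` (normally thresholded).
#' @return A symmetric numeric matrix of pair weights.
#' @export
symmetrize_proximity <- function(pnet) {
  stopifnot(inherits(pnet, "proximity_network"))
  pnet$prox + t(pnet$prox)
}
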