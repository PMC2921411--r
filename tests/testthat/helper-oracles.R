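# Fixture builders and independent oracles shared across the suite.

# random weighted network; unit weights unless weighted = TRUE
rand_network <- function(n, p = 0.5, directed = FALSE, weighted = FALSE) {
  nodes <- paste0("v", seq_len(n))
  A <- matrix(0, n, n, dimnames = list(nodes, nodes))
  if (directed) {
    mask <- matrix(stats::runif(n * n) < p, n, n)
    diag(mask) <- FALSE
    A[mask] <- if (weighted) stats::runif(sum(mask), 0.5, 3) else 1
  } else {
    ut <- upper.tri(A)
    mask <- ut & matrix(stats::runif(n * n) < p, n, n)
    A[mask] <- if (weighted) stats::runif(sum(mask), 0.5, 3) else 1
    A <- A + t(A)
  }
  weighted_network(A, directed = directed)
}

# two k-cliques of weight w joined by a single bridge of weight bw
two_cliques <- function(k = 3, w = 5, bw = 1) {
  n <- 2 * k
  nodes <- letters[seq_len(n)]
  A <- matrix(0, n, n, dimnames = list(nodes, nodes))
  A[1:k, 1:k] <- w
  A[(k + 1):n, (k + 1):n] <- w
  diag(A) <- 0
  A[k, k + 1] <- A[k + 1, k] <- bw
  weighted_network(A, directed = FALSE)
}

# direct re-statement of the proximity formula as an explicit loop over
# two-step paths; independent of the vectorized implementation
brute_prox <- function(A, i, j) {
  W <- rowSums(A)
  s <- A[i, j]
  for (k in seq_len(nrow(A))) {
    if (k == i || k == j) next
    if (A[i, k] > 0 && A[k, j] > 0)
      s <- s + (A[i, k] / (W[i] - A[i, j])) * (A[k, j] / W[k]) *
        min(A[i, k], A[k, j])
  }
  unname(s)
}

# exhaustive maximum spanning forest weight: per component, enumerate all
# edge subsets of size (|component| - 1) and keep the heaviest spanning one
brute_msf_weight <- function(W) {
  n <- nrow(W)
  comp <- rep(0L, n)
  cid <- 0L
  for (s in seq_len(n)) {
    if (comp[s] > 0L) next
    cid <- cid + 1L
    queue <- s
    comp[s] <- cid
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      nb <- which(W[v, ] > 0 & comp == 0L)
      comp[nb] <- cid
      queue <- c(queue, nb)
    }
  }
  total <- 0
  for (cc in seq_len(cid)) {
    verts <- which(comp == cc)
    k <- length(verts)
    if (k < 2) next
    idx <- which(W > 0 & upper.tri(W), arr.ind = TRUE)
    idx <- idx[idx[, 1] %in% verts & idx[, 2] %in% verts, , drop = FALSE]
    best <- -Inf
    for (sub in utils::combn(seq_len(nrow(idx)), k - 1, simplify = FALSE)) {
      parent <- seq_len(n)
      find <- function(x) { while (parent[x] != x) x <- parent[x]; x }
      acyclic <- TRUE
      for (e in sub) {
        ra <- find(idx[e, 1]); rb <- find(idx[e, 2])
        if (ra == rb) { acyclic <- FALSE; break }
        parent[ra] <- rb
      }
      if (acyclic) {
        wsum <- sum(W[idx[sub, , drop = FALSE]])
        if (wsum > best) best <- wsum
      }
    }
    total <- total + best
  }
  total
}

# pairwise partition-criterion check on a module set: for every module
# pair with positive mutual proximity, each intra sum must exceed the
# inter sum in both directions
criterion_holds <- function(ms, pnet) {
  P <- pnet$prox[names(ms$membership), names(ms$membership), drop = FALSE]
  mods <- ms$modules
  p <- length(mods)
  if (p < 2) return(TRUE)
  for (a in seq_len(p - 1)) for (b in (a + 1):p) {
    iab <- sum(P[mods[[a]], mods[[b]]])
    iba <- sum(P[mods[[b]], mods[[a]]])
    inter <- max(iab, iba)
    if (inter == 0) next
    if (sum(P[mods[[a]], mods[[a]]]) <= inter) return(FALSE)
    if (sum(P[mods[[b]], mods[[b]]]) <= inter) return(FALSE)
  }
  TRUE
}

# upper-tail hypergeometric probability by direct combinatorial enumeration
brute_hyper <- function(k, n, K, N) {
  xs <- k:min(n, K)
  sum(choose(K, xs) * choose(N - K, n - xs)) / choose(N, n)
}

# proximity_network wrapper around a raw matrix (internal-contract fixture)
as_pnet <- function(P, directed = TRUE) {
  structure(list(prox = P, directed = directed,
                 zscores = NULL, threshold_applied = NULL),
            class = "proximity_network")
}
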