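#' Maximum-spanning-forest backbone
#'
#' Extracts one maximum-weight spanning tree per connected component of the
#' symmetrized, thresholded proximity graph (Kruskal's algorithm). The forest
#' connects all nodes of each component with the maximum total pair weight
#' and serves as the backbone restricting the partition search space.
#' Isolated nodes become single-node trees. Ties are broken
#' deterministically: edges are processed by decreasing weight, then by
#' lexicographic order of their (sorted) endpoint names, so repeated runs
#' produce identical backbones.
#'
#' @param weights Symmetric numeric matrix of non-negative pair weights with
#'   node names as dimnames (see [symmetrize_proximity()]); zero means no
#'   link.
#' @param nodes Optional character vector of node names to cover; defaults
#'   to the row names of `weights`.
#' @return An object of class `backbone`: a list with `nodes`, `edges`
#'   (data.frame `from`, `to`, `weight` of forest edges), `tree_id`
#'   (named integer vector mapping each node to its tree), and `n_trees`.
#' @export
maximum_spanning_forest <- function(weights, nodes = rownames(weights)) {
  if (!is.matrix(weights) || is.null(rownames(weights)))
    stop("'weights' must be a named square matrix")
  if (any(weights < 0)) stop("pair weights must be non-negative")
  nodes <- as.character(nodes)
  W <- weights[nodes, nodes, drop = FALSE]
  n <- length(nodes)
  idx <- which(W > 0 & upper.tri(W), arr.ind = TRUE)
  e_from <- idx[, 1]; e_to <- idx[, 2]; e_w <- W[idx]
  nm1 <- pmin(nodes[e_from], nodes[e_to])
  nm2 <- pmax(nodes[e_from], nodes[e_to])
  ord <- order(-e_w, nm1, nm2)

  parent <- seq_len(n)
  find <- function(x) {
    while (parent[x] != x) {
      parent[x] <<- parent[parent[x]]
      x <- parent[x]
    }
    x
  }
  keep <- logical(length(ord))
  for (e in ord) {
    ra <- find(e_from[e]); rb <- find(e_to[e])
    if (ra != rb) {
      parent[ra] <- rb
      keep[e] <- TRUE
    }
  }
  sel <- which(keep)
  edges <- data.frame(from = nodes[e_from[sel]], to = nodes[e_to[sel]],
                      weight = e_w[sel], stringsAsFactors = FALSE)
  roots <- vapply(seq_len(n), find, integer(1))
  tree_id <- match(roots, unique(roots))
  names(tree_id) <- nodes
  structure(list(nodes = nodes, edges = edges, tree_id = tree_id,
                 n_trees = max(tree_id)),
            class = "backbone")
}

#' @export
print.backbone <- function(x, ...) {
  cat(sprintf("Backbone: %d nodes, %d edges, %d tree(s)\n",
              length(x$nodes), nrow(x$edges), x$n_trees))
  invisible(x)
}

# ordered-pair proximity totals between modules of a membership vector:
# G[a, b] = sum_{i in a, j in b} P[i, j]
.module_cross_sums <- function(P, memb) {
  f <- factor(memb)
  M1 <- rowsum(P, f, reorder = TRUE)
  G <- t(rowsum(t(M1), f, reorder = TRUE))
  dimnames(G) <- list(levels(f), levels(f))
  G
}

# Merge modules (list of integer index vectors into P) violating the
# intra/inter criterion, smallest violation first, until none remains.
# A pair with zero inter-module proximity never violates (isolated
# singletons are legitimate); ties break on module order.
.repair_modules <- function(modules, P) {
  if (length(modules) <= 1L) return(modules)
  all_idx <- unlist(modules)
  memb <- rep(seq_along(modules), lengths(modules))
  Psub <- P[all_idx, all_idx, drop = FALSE]
  repeat {
    G <- .module_cross_sums(Psub, memb)
    p <- nrow(G)
    if (p <= 1L) break
    intra <- diag(G)
    inter <- pmax(G, t(G)); diag(inter) <- 0
    bad <- inter > 0 &
      (matrix(intra, p, p) <= inter | matrix(intra, p, p, byrow = TRUE) <= inter)
    viol <- which(bad & upper.tri(bad), arr.ind = TRUE)
    if (!nrow(viol)) break
    mag <- inter[viol] - pmin(intra[viol[, 1]], intra[viol[, 2]])
    pick <- viol[order(mag, viol[, 1], viol[, 2])[1], ]
    ga <- as.integer(rownames(G)[pick[1]]); gb <- as.integer(rownames(G)[pick[2]])
    memb[memb == gb] <- ga
  }
  ids <- sort(unique(memb))
  lapply(ids, function(m) all_idx[memb == m])
}

# Divisive partitioning by validated link removal. Starting from one
# module per backbone tree, tree links are examined from weakest to
# strongest (ties by lexicographic endpoint names): a link is tentatively
# removed, splitting its module T into sub-trees A and B, and the removal
# is committed only if the resulting global module set still satisfies the
# partition criterion -- each new module's intra-module proximity sum must
# exceed its inter-module proximity sum, in both directions, against the
# other new module and every existing module (pairs with zero mutual
# proximity are exempt; existing pairs stay valid because splitting can
# only lower their inter sums). Refused links are restored; passes repeat
# until no link can be removed, so the final module set satisfies the
# criterion pairwise by induction.
.remove_links_pass <- function(memb, edges, P, labels) {
  n <- length(memb)
  # cached outgoing/incoming proximity mass per module (module id -> n-vector)
  colmass <- list(); rowmass <- list()
  for (m in unique(memb)) {
    T_ <- which(memb == m)
    colmass[[as.character(m)]] <- colSums(P[T_, , drop = FALSE])
    rowmass[[as.character(m)]] <- rowSums(P[, T_, drop = FALSE])
  }
  repeat {
    removed_any <- FALSE
    ew <- P[edges] + P[edges[, c(2, 1), drop = FALSE]]
    n1 <- pmin(labels[edges[, 1]], labels[edges[, 2]])
    n2 <- pmax(labels[edges[, 1]], labels[edges[, 2]])
    drop_edge <- logical(nrow(edges))
    for (e in order(ew, n1, n2)) {
      mod <- memb[edges[e, 1]]
      key <- as.character(mod)
      in_mod <- which(memb == mod)
      if (length(in_mod) <= 1L) next
      me <- which(memb[edges[, 1]] == mod & !drop_edge)
      me <- me[me != e]
      # component of endpoint 1 within the module, excluding link e
      nbr <- vector("list", n)
      for (r in me) {
        nbr[[edges[r, 1]]] <- c(nbr[[edges[r, 1]]], edges[r, 2])
        nbr[[edges[r, 2]]] <- c(nbr[[edges[r, 2]]], edges[r, 1])
      }
      seen <- rep(FALSE, n)
      queue <- edges[e, 1]; seen[queue] <- TRUE; A <- queue
      while (length(queue)) {
        v <- queue[[1]]; queue <- queue[-1]
        nb <- nbr[[v]]; nb <- nb[!seen[nb]]
        seen[nb] <- TRUE
        A <- c(A, nb); queue <- c(queue, nb)
      }
      B <- setdiff(in_mod, A)
      S <- if (length(A) <= length(B)) A else B
      colS <- colSums(P[S, , drop = FALSE])
      rowS <- rowSums(P[, S, drop = FALSE])
      colO <- colmass[[key]] - colS
      rowO <- rowmass[[key]] - rowS
      if (identical(S, A)) {
        colA <- colS; rowA <- rowS; colB <- colO; rowB <- rowO
      } else {
        colB <- colS; rowB <- rowS; colA <- colO; rowA <- rowO
      }
      grp <- memb
      grp[A] <- -1L; grp[B] <- -2L
      f <- factor(grp)
      lv <- levels(f)
      aggA_out <- rowsum(colA, f); aggA_in <- rowsum(rowA, f)
      aggB_out <- rowsum(colB, f); aggB_in <- rowsum(rowB, f)
      ia <- which(lv == "-1"); ib <- which(lv == "-2")
      intra_A <- aggA_out[ia]; intra_B <- aggB_out[ib]
      interA <- pmax(aggA_out[-ia], aggA_in[-ia])
      interB <- pmax(aggB_out[-ib], aggB_in[-ib])
      if (all(interA < intra_A | interA == 0) &&
          all(interB < intra_B | interB == 0)) {
        new_id <- max(memb) + 1L
        memb[B] <- new_id
        colmass[[key]] <- colA; rowmass[[key]] <- rowA
        colmass[[as.character(new_id)]] <- colB
        rowmass[[as.character(new_id)]] <- rowB
        drop_edge[e] <- TRUE
        removed_any <- TRUE
      }
    }
    edges <- edges[!drop_edge, , drop = FALSE]
    if (!removed_any || nrow(edges) == 0L) break
  }
  memb
}

#' Partition a network along its backbone
#'
#' Divisive top-down partitioning guided by the backbone: starting from one
#' module per backbone tree, tree links are examined from weakest to
#' strongest; each is tentatively removed, splitting its module into the two
#' sub-trees on either side, and the removal is committed only if the
#' resulting module set still satisfies the partition criterion -- each new
#' module's intra-module proximity sum must exceed the inter-module
#' proximity sum, in each direction, against the other new module and every
#' existing module. All sums are taken over the full thresholded proximity
#' network, not the tree. Refused links are restored, and passes over the
#' remaining links repeat until no further removal is possible, so the
#' final module set satisfies the criterion pairwise by construction.
#' Module pairs with zero mutual proximity are exempt (a module may be
#' unrelated to a distant one); singleton modules with zero proximity to
#' every other module are kept and flagged as isolated. A final validation
#' pass re-checks all module pairs and would merge any violating pair,
#' smallest violation first; it is a safety net that normal runs leave
#' untouched.
#'
#' @param backbone A [maximum_spanning_forest()] result.
#' @param pnet The thresholded `proximity_network` the backbone was built
#'   from (shares its node set).
#' @return An object of class `module_set`: a list with `modules` (named
#'   list of node-name vectors), `membership` (named character vector,
#'   node -> module id), `s_intra` (per-module intra sums), `s_inter`
#'   (module-pair matrix of the binding inter sums, the larger of the two
#'   directions), and
#'   `isolated` (ids of flagged isolated singleton modules).
#' @export
partition_backbone <- function(backbone, pnet) {
  stopifnot(inherits(backbone, "backbone"), inherits(pnet, "proximity_network"))
  P <- pnet$prox
  nodes <- backbone$nodes
  if (!setequal(nodes, rownames(P)))
    stop("backbone and proximity network must share the same node set")
  P <- P[nodes, nodes, drop = FALSE]
  labels <- nodes
  symw <- P + t(P)

  edge_idx <- cbind(match(backbone$edges$from, nodes),
                    match(backbone$edges$to, nodes))
  memb0 <- as.integer(backbone$tree_id)
  memb0 <- .remove_links_pass(memb0, edge_idx, P, labels)
  modules <- split(seq_along(nodes), memb0)
  modules <- .repair_modules(modules, P)

  # deterministic module order and ids: by first member in node order
  modules <- modules[order(vapply(modules, min, 0L))]
  mod_ids <- as.character(seq_along(modules))
  memb <- integer(length(nodes))
  for (m in seq_along(modules)) memb[modules[[m]]] <- m
  modules <- lapply(modules, function(m) labels[m])
  names(modules) <- mod_ids
  membership <- stats::setNames(mod_ids[memb], labels)
  G <- .module_cross_sums(P, memb)
  ord <- match(as.character(seq_along(mod_ids)), rownames(G))
  G <- G[ord, ord, drop = FALSE]
  s_intra <- stats::setNames(diag(G), mod_ids)
  s_inter <- pmax(G, t(G)); diag(s_inter) <- 0
  dimnames(s_inter) <- list(mod_ids, mod_ids)
  isolated <- mod_ids[s_intra == 0 & rowSums(s_inter) == 0]
  structure(list(modules = modules, membership = membership,
                 s_intra = s_intra, s_inter = s_inter, isolated = isolated),
            class = "module_set")
}

#' @export
print.module_set <- function(x, ...) {
  sz <- lengths(x$modules)
  cat(sprintf("Module set: %d modules over %d nodes (sizes %s)%s\n",
              length(x$modules), sum(sz),
              paste(utils::head(sort(sz, decreasing = TRUE), 8), collapse = ", "),
              if (length(x$isolated)) sprintf("; %d isolated", length(x$isolated)) else ""))
  invisible(x)
}
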