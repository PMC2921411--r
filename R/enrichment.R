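#' Annotation table for module enrichment
#'
#' Pairs nodes with annotation categories for the generic enrichment
#' statistics. The background (the universe for the hypergeometric test)
#' defaults to all annotated nodes.
#'
#' @param pairs A data.frame with columns `node_id` and `category_id`, one
#'   row per node/category pair (a node may carry several categories).
#' @param background Optional character vector of background node ids;
#'   every annotated node must belong to it.
#' @return An object of class `annotation_table`: a list with `membership`
#'   (named list: node -> character vector of categories) and `background`.
#' @export
annotation_table <- function(pairs, background = NULL) {
  if (!all(c("node_id", "category_id") %in% names(pairs)))
    stop("'pairs' must have columns 'node_id' and 'category_id'")
  pairs$node_id <- as.character(pairs$node_id)
  pairs$category_id <- as.character(pairs$category_id)
  membership <- lapply(split(pairs$category_id, pairs$node_id), unique)
  if (is.null(background)) background <- names(membership)
  background <- as.character(background)
  if (!all(names(membership) %in% background))
    stop("every annotated node must be in the background")
  structure(list(membership = membership, background = background),
            class = "annotation_table")
}

#' Read an annotation table from a TSV file
#'
#' Expects two tab-separated columns, `node_id` and `category_id`, one row
#' per pair; a header line is optional (detected by the literal column
#' names). Lines starting with `#` are skipped.
#'
#' @param path Path to the TSV file.
#' @param background Optional background node set (see [annotation_table()]).
#' @return An [annotation_table()].
#' @export
read_annotations <- function(path, background = NULL) {
  df <- utils::read.table(path, sep = "\t", header = FALSE, comment.char = "#",
                          col.names = c("node_id", "category_id"),
                          colClasses = "character")
  if (nrow(df) && df$node_id[1] == "node_id") df <- df[-1, , drop = FALSE]
  annotation_table(df, background = background)
}

#' Upper-tail hypergeometric p-value
#'
#' Probability of observing `k` or more category members in a module under
#' random assignment: `P(X >= k)` for `X ~ Hypergeometric(N, K, n)` with
#' `N` background nodes of which `K` carry the category, and a module of
#' `n` background nodes. Computed via the survival function for numerical
#' stability.
#'
#' @param k Observed category members in the module.
#' @param n Module size (annotated members only).
#' @param K Category size in the background.
#' @param N Background size.
#' @return A p-value in `(0, 1]`.
#' @export
hypergeometric_pvalue <- function(k, n, K, N) {
  if (any(c(k, n, K, N) < 0) || k > min(n, K) || n > N || K > N)
    stop("inconsistent hypergeometric counts")
  if (k == 0) return(1)
  stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
}

#' Enrichment of one module against an annotation table
#'
#' For every category with at least one member in the module, the
#' upper-tail hypergeometric p-value of the observed overlap is computed
#' over the annotated background. By the common raw-reporting convention no
#' multiple-testing correction is applied by default; Bonferroni across the
#' tested categories is available.
#'
#' @param module Character vector of node ids.
#' @param annotations An [annotation_table()].
#' @param correction `"none"` (default) or `"bonferroni"`.
#' @return A list with `best_category`, `best_p`, and `table` (data.frame
#'   of per-category counts and p-values, sorted by p). If the module has
#'   no annotated member, a no-annotation result (`best_category = NA`,
#'   `best_p = NA`, empty table) is returned.
#' @export
module_enrichment <- function(module, annotations,
                              correction = c("none", "bonferroni")) {
  stopifnot(inherits(annotations, "annotation_table"))
  correction <- match.arg(correction)
  bg <- annotations$background
  memb <- annotations$membership
  mod_ann <- intersect(as.character(module), names(memb))
  if (!length(mod_ann))
    return(list(best_category = NA_character_, best_p = NA_real_,
                table = data.frame(category = character(0), k = integer(0),
                                   n = integer(0), K = integer(0),
                                   N = integer(0), p = numeric(0))))
  N <- length(bg)
  n <- length(intersect(as.character(module), bg))
  cats <- sort(unique(unlist(memb[mod_ann], use.names = FALSE)))
  cat_sizes <- table(unlist(memb, use.names = FALSE))
  rows <- lapply(cats, function(cc) {
    k <- sum(vapply(memb[mod_ann], function(v) cc %in% v, logical(1)))
    K <- as.integer(cat_sizes[[cc]])
    data.frame(category = cc, k = k, n = n, K = K, N = N,
               p = hypergeometric_pvalue(k, n, K, N))
  })
  tab <- do.call(rbind, rows)
  if (correction == "bonferroni") tab$p <- pmin(1, tab$p * nrow(tab))
  tab <- tab[order(tab$p, tab$category), ]
  rownames(tab) <- NULL
  list(best_category = tab$category[1], best_p = tab$p[1], table = tab)
}

#' Ratio of p-value decrease after merging two modules
#'
#' `(min(pv_a, pv_b) - pv_ab) / min(pv_a, pv_b)`: positive exactly when the
#' merged module's enrichment p-value `pv_ab` is smaller than both parents',
#' i.e. when the merge is more significant than either module alone.
#'
#' @param pv_a,pv_b Enrichment p-values of the two modules, in (0, 1].
#' @param pv_ab Enrichment p-value of the merged module, in (0, 1].
#' @return The decrease ratio (at most 1).
#' @export
p_decrease_ratio <- function(pv_a, pv_b, pv_ab) {
  if (any(c(pv_a, pv_b, pv_ab) <= 0) || any(c(pv_a, pv_b, pv_ab) > 1))
    stop("p-values must lie in (0, 1]")
  m <- min(pv_a, pv_b)
  (m - pv_ab) / m
}

# one-sided exact binomial tail P(X >= successes) under chance 1/2
.sign_test_pvalue <- function(successes, trials) {
  stats::pbinom(successes - 1L, trials, 0.5, lower.tail = FALSE)
}

#' Sign test: does supernode proximity track annotation coherence?
#'
#' Tests, at one pyramid level, whether pairs of modules with greater
#' mutual proximity show a larger enrichment gain when merged. For every
#' ordered pair of abstract-network links `(a, b)` and `(c, d)` with
#' strictly greater symmetrized proximity `P_ab > P_cd`, a success is
#' recorded when the [p_decrease_ratio()] of merging `a` with `b` exceeds
#' that of merging `c` with `d`; ties in the ratio are excluded. The
#' success count is tested against chance 1/2 with a one-sided exact
#' binomial sign test.
#'
#' @param pyramid A [build_pyramid()] result.
#' @param level Level number (1 = top) whose abstract network is tested.
#' @param annotations An [annotation_table()] over the original nodes.
#' @param alpha Significance level (default 0.01).
#' @param max_pairs Optional cap on the number of link pairs compared (the
#'   first `max_pairs` in deterministic link order); `Inf` compares all.
#' @return A list with `successes`, `trials`, `p_value`, `significant`,
#'   `alpha`, and `links` (the per-link merge statistics). If fewer than
#'   two links with distinct proximities (or usable p-values) exist, a
#'   result with `insufficient_data = TRUE` is returned.
#' @export
proximity_signtest <- function(pyramid, level, annotations, alpha = 0.01,
                               max_pairs = Inf) {
  stopifnot(inherits(pyramid, "pyramid"), inherits(annotations, "annotation_table"))
  k <- pyramid$n_levels
  li <- k - level + 1L
  if (li < 1L || li > k) stop("level out of range")
  lev <- pyramid$levels[[li]]
  W <- lev$abstract_network$adjacency
  Wsym <- W + t(W)
  flat <- flatten_membership(pyramid, level)
  members <- split(names(flat), flat)

  idx <- which(Wsym > 0 & upper.tri(Wsym), arr.ind = TRUE)
  insufficient <- list(successes = NA_integer_, trials = 0L,
                       p_value = NA_real_, significant = FALSE,
                       alpha = alpha, insufficient_data = TRUE)
  if (nrow(idx) < 2) return(insufficient)
  a <- rownames(Wsym)[idx[, 1]]
  b <- colnames(Wsym)[idx[, 2]]
  w <- Wsym[idx]
  ord <- order(-w, pmin(a, b), pmax(a, b))
  a <- a[ord]; b <- b[ord]; w <- w[ord]

  mod_p <- vapply(names(members), function(m)
    module_enrichment(members[[m]], annotations)$best_p, numeric(1))
  ratio <- rep(NA_real_, length(w))
  for (e in seq_along(w)) {
    pv_a <- mod_p[[a[e]]]; pv_b <- mod_p[[b[e]]]
    if (is.na(pv_a) || is.na(pv_b)) next
    pv_ab <- module_enrichment(c(members[[a[e]]], members[[b[e]]]),
                               annotations)$best_p
    ratio[e] <- p_decrease_ratio(pv_a, pv_b, pv_ab)
  }
  links <- data.frame(module_a = a, module_b = b, proximity = w,
                      decrease_ratio = ratio)

  usable <- which(!is.na(ratio))
  succ <- 0L; trials <- 0L
  done <- FALSE
  for (i in usable) {
    for (j in usable) {
      if (w[i] > w[j]) {           # strict proximity inequality only
        if (ratio[i] == ratio[j]) next  # ties excluded
        trials <- trials + 1L
        if (ratio[i] > ratio[j]) succ <- succ + 1L
        if (trials >= max_pairs) { done <- TRUE; break }
      }
    }
    if (done) break
  }
  if (trials < 1L) return(insufficient)
  p <- .sign_test_pvalue(succ, trials)
  list(successes = succ, trials = trials, p_value = p,
       significant = p <= alpha, alpha = alpha,
       insufficient_data = FALSE, links = links)
}
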