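#' Weighted network
#'
#' Construct a weighted, optionally directed network over named nodes from an
#' adjacency matrix. This is the container every other function in the package
#' consumes: the input network at the bottom of a pyramid, and the abstract
#' supernode network at every level above it.
#'
#' @param adjacency Square numeric matrix of non-negative link weights with
#'   identical row and column names (node identifiers, opaque strings).
#'   `adjacency[i, j]` is the weight of the link from node `i` to node `j`;
#'   zero means no link. The diagonal must be zero (self-links are not
#'   representable; see [read_edge_list()] for how they are handled on input).
#' @param directed Logical; if `FALSE` the matrix must be symmetric.
#' @return An object of class `weighted_network`: a list with elements
#'   `adjacency` (the validated matrix) and `directed`.
#' @seealso [read_edge_list()], [compute_proximity()], [network_density()]
#' @export
weighted_network <- function(adjacency, directed = FALSE) {
  if (!is.matrix(adjacency) || !is.numeric(adjacency))
    stop("'adjacency' must be a numeric matrix")
  if (nrow(adjacency) != ncol(adjacency))
    stop("'adjacency' must be square")
  if (is.null(rownames(adjacency)))
    rownames(adjacency) <- colnames(adjacency) <- as.character(seq_len(nrow(adjacency)))
  if (!identical(rownames(adjacency), colnames(adjacency)))
    stop("row and column names of 'adjacency' must be identical node identifiers")
  if (anyDuplicated(rownames(adjacency)))
    stop("duplicate node identifiers")
  if (any(adjacency < 0))
    stop("link weights must be non-negative")
  if (any(diag(adjacency) != 0))
    stop("self-links are not allowed (non-zero diagonal)")
  if (!directed && !isTRUE(all.equal(adjacency, t(adjacency), check.attributes = FALSE)))
    stop("undirected network requires a symmetric adjacency matrix")
  structure(list(adjacency = adjacency, directed = isTRUE(directed)),
            class = "weighted_network")
}

#' @export
print.weighted_network <- function(x, ...) {
  n <- nrow(x$adjacency)
  L <- n_links(x)
  cat(sprintf("Weighted %s network: %d nodes, %d links\n",
              if (x$directed) "directed" else "undirected", n, L))
  invisible(x)
}

#' Network accessors
#'
#' Small accessors for [weighted_network()] objects: node identifiers,
#' node count, and stored link count (ordered pairs for directed networks,
#' unordered pairs for undirected ones).
#'
#' @param net A [weighted_network()].
#' @return `node_names()`: character vector; `n_nodes()`, `n_links()`:
#'   single integers.
#' @export
node_names <- function(net) rownames(net$adjacency)

#' @rdname node_names
#' @export
n_nodes <- function(net) nrow(net$adjacency)

#' @rdname node_names
#' @export
n_links <- function(net) {
  nz <- sum(net$adjacency > 0)
  if (net$directed) nz else nz / 2L
}

#' Edge density of a network
#'
#' Fraction of realized links among all possible node pairs, ignoring
#' weights: `2L / (n (n - 1))` for undirected networks with `L` stored
#' unordered links, `L / (n (n - 1))` for directed ones.
#'
#' @param net A [weighted_network()].
#' @return A single number in `[0, 1]`.
#' @export
network_density <- function(net) {
  stopifnot(inherits(net, "weighted_network"))
  n <- n_nodes(net)
  if (n < 2) stop("density is undefined for networks with fewer than 2 nodes")
  if (net$directed) n_links(net) / (n * (n - 1)) else 2 * n_links(net) / (n * (n - 1))
}

#' Read a network from an edge-list file
#'
#' Parses a whitespace/tab-separated edge list with two or three fields per
#' line (`source target [weight]`). Lines starting with `#` and blank lines
#' are ignored. Node identifiers are kept as opaque strings in order of first
#' appearance. Self-links are dropped with a warning; duplicate links are
#' merged by summing their weights, with a warning, so repeated records add
#' up rather than overwrite.
#'
#' @param path Path to the edge-list file.
#' @param directed Logical; if `FALSE` each record stores both directions.
#' @param default_weight Weight assigned to two-field records (default 1, the
#'   convention for unweighted interaction networks).
#' @return A [weighted_network()].
#' @export
read_edge_list <- function(path, directed = FALSE, default_weight = 1) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  keep <- !grepl("^\\s*(#|$)", lines)
  idx <- which(keep)
  recs <- strsplit(trimws(lines[keep]), "\\s+")
  nf <- lengths(recs)
  if (any(bad <- nf < 2 | nf > 3))
    stop(sprintf("malformed edge record at line %d: expected 2 or 3 fields, got %d",
                 idx[which(bad)[1]], nf[which(bad)[1]]))
  from <- vapply(recs, `[[`, "", 1L)
  to   <- vapply(recs, `[[`, "", 2L)
  w    <- rep(as.numeric(default_weight), length(recs))
  has_w <- nf == 3L
  if (any(has_w)) {
    wv <- suppressWarnings(as.numeric(vapply(recs[has_w], `[[`, "", 3L)))
    if (anyNA(wv))
      stop(sprintf("non-numeric weight at line %d", idx[has_w][which(is.na(wv))[1]]))
    w[has_w] <- wv
  }
  if (any(w < 0))
    stop(sprintf("negative weight at line %d", idx[which(w < 0)[1]]))

  self <- from == to
  if (any(self)) {
    warning(sprintf("dropped %d self-link(s) (first at line %d)",
                    sum(self), idx[which(self)[1]]))
    from <- from[!self]; to <- to[!self]; w <- w[!self]
  }

  nodes <- unique(c(rbind(from, to)))
  A <- matrix(0, length(nodes), length(nodes), dimnames = list(nodes, nodes))
  key <- if (directed) paste(from, to) else paste(pmin(from, to), pmax(from, to))
  if (anyDuplicated(key))
    warning(sprintf("merged %d duplicate link record(s) by summing weights",
                    sum(duplicated(key))))
  for (r in seq_along(from)) {
    A[from[r], to[r]] <- A[from[r], to[r]] + w[r]
    if (!directed) A[to[r], from[r]] <- A[to[r], from[r]] + w[r]
  }
  weighted_network(A, directed = directed)
}

#' Write a network as an edge-list file
#'
#' Inverse of [read_edge_list()]: one `source target weight` record per
#' stored link (unordered pairs once for undirected networks), tab-separated.
#'
#' @param net A [weighted_network()].
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_edge_list <- function(net, path) {
  stopifnot(inherits(net, "weighted_network"))
  A <- net$adjacency
  if (net$directed) {
    idx <- which(A > 0, arr.ind = TRUE)
  } else {
    idx <- which(A > 0 & upper.tri(A), arr.ind = TRUE)
  }
  df <- data.frame(from = rownames(A)[idx[, 1]],
                   to   = colnames(A)[idx[, 2]],
                   weight = A[idx])
  df <- df[order(df$from, df$to), ]
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
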