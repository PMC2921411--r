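#' Write a pyramid to a directory
#'
#' Emits, per level in printed order (level 1 = top): a membership TSV
#' (`membership_level<k>.tsv`, columns `node_id` and `module_id` over the
#' level's input nodes) and an abstract-network edge list
#' (`abstract_level<k>.tsv`, columns `module_i`, `module_j`, `proximity`),
#' plus a single `pyramid.json` holding the levels (modules, abstract
#' edges, child-to-parent maps), the bottom-level input edges, and the run
#' parameters. [read_pyramid()] restores the structure from the JSON.
#'
#' @param pyramid A [build_pyramid()] result.
#' @param out_dir Output directory; created if missing.
#' @return Invisibly, the character vector of files written.
#' @export
write_pyramid <- function(pyramid, out_dir) {
  stopifnot(inherits(pyramid, "pyramid"))
  if (!dir.exists(out_dir) && !dir.create(out_dir, recursive = TRUE))
    stop("cannot create output directory: ", out_dir)
  k <- pyramid$n_levels
  files <- character(0)
  net_edges <- function(net) {
    A <- net$adjacency
    idx <- if (net$directed) which(A > 0, arr.ind = TRUE)
           else which(A > 0 & upper.tri(A), arr.ind = TRUE)
    df <- data.frame(from = rownames(A)[idx[, 1]], to = colnames(A)[idx[, 2]],
                     weight = A[idx])
    df[order(df$from, df$to), , drop = FALSE]
  }
  levels_json <- vector("list", k)
  for (lv in seq_len(k)) {           # printed numbering: 1 = top
    li <- k - lv + 1L
    level <- pyramid$levels[[li]]
    memb <- data.frame(node_id = names(level$parent_of),
                       module_id = unname(level$parent_of))
    fm <- file.path(out_dir, sprintf("membership_level%d.tsv", lv))
    utils::write.table(memb, fm, sep = "\t", quote = FALSE, row.names = FALSE)
    ae <- net_edges(level$abstract_network)
    names(ae) <- c("module_i", "module_j", "proximity")
    fa <- file.path(out_dir, sprintf("abstract_level%d.tsv", lv))
    utils::write.table(ae, fa, sep = "\t", quote = FALSE, row.names = FALSE)
    files <- c(files, fm, fa)
    # the JSON always stores both directions so the reader is agnostic of
    # the abstract network's directedness
    Aabs <- level$abstract_network$adjacency
    full <- which(Aabs > 0, arr.ind = TRUE)
    ae_full <- data.frame(module_i = rownames(Aabs)[full[, 1]],
                          module_j = colnames(Aabs)[full[, 2]],
                          proximity = Aabs[full])
    ae_full <- ae_full[order(ae_full$module_i, ae_full$module_j), , drop = FALSE]
    levels_json[[lv]] <- list(
      level = lv,
      modules = lapply(level$module_set$modules, as.list),
      parent_of = as.list(level$parent_of),
      isolated = as.list(level$module_set$isolated),
      abstract_edges = ae_full)
  }
  bottom <- pyramid$levels[[1L]]$input_network
  obj <- list(
    levels = levels_json,
    input_network = list(nodes = node_names(bottom),
                         edges = net_edges(bottom),
                         directed = bottom$directed),
    params = pyramid$params,
    stalled = pyramid$stalled)
  fj <- file.path(out_dir, "pyramid.json")
  jsonlite::write_json(obj, fj, auto_unbox = TRUE, digits = NA, null = "null")
  files <- c(files, fj)
  invisible(files)
}

#' Read a pyramid written by [write_pyramid()]
#'
#' Restores the pyramid structure from `pyramid.json`: level memberships,
#' abstract networks, the bottom-level input network, run parameters and
#' the stall flag. The per-level intra/inter proximity scores are not
#' serialized and come back as `NULL`.
#'
#' @param dir Directory containing `pyramid.json`.
#' @return A `pyramid` object.
#' @export
read_pyramid <- function(dir) {
  path <- file.path(dir, "pyramid.json")
  if (!file.exists(path)) stop("no pyramid.json in ", dir)
  obj <- jsonlite::read_json(path, simplifyVector = FALSE)
  edges_to_net <- function(nodes, edge_rows, fields, directed) {
    A <- matrix(0, length(nodes), length(nodes), dimnames = list(nodes, nodes))
    for (e in edge_rows) {
      A[e[[fields[1]]], e[[fields[2]]]] <- as.numeric(e[[fields[3]]])
      if (!directed)
        A[e[[fields[2]]], e[[fields[1]]]] <- as.numeric(e[[fields[3]]])
    }
    weighted_network(A, directed = directed)
  }
  directed <- isTRUE(obj$input_network$directed)
  nodes <- vapply(obj$input_network$nodes, as.character, "")
  current <- edges_to_net(nodes, obj$input_network$edges,
                          c("from", "to", "weight"), directed)
  k <- length(obj$levels)
  levels <- vector("list", k)
  for (lv in rev(seq_len(k))) {      # JSON is top-first; rebuild bottom-up
    lj <- obj$levels[[lv]]
    modules <- lapply(lj$modules, function(m) vapply(m, as.character, ""))
    parent_of <- vapply(lj$parent_of, as.character, "")
    ms <- structure(list(modules = modules,
                         membership = parent_of[node_names(current)],
                         s_intra = NULL, s_inter = NULL,
                         isolated = vapply(lj$isolated, as.character, "")),
                    class = "module_set")
    names(ms$membership) <- node_names(current)
    abs_net <- edges_to_net(names(modules), lj$abstract_edges,
                            c("module_i", "module_j", "proximity"),
                            directed = TRUE)
    # abstract networks are stored as directed edge lists; restore the
    # undirected flag only when the matrix came back symmetric
    if (isTRUE(all.equal(abs_net$adjacency, t(abs_net$adjacency),
                         check.attributes = FALSE)))
      abs_net <- weighted_network(
        (abs_net$adjacency + t(abs_net$adjacency)) / 2, directed = FALSE)
    levels[[k - lv + 1L]] <- list(input_network = current, module_set = ms,
                                  abstract_network = abs_net,
                                  parent_of = ms$membership)
    current <- abs_net
  }
  params <- obj$params
  structure(list(levels = levels, params = list(
    z_threshold = as.numeric(params$z_threshold),
    directed = isTRUE(params$directed),
    max_levels = as.integer(params$max_levels),
    seed = if (is.null(params$seed)) NULL else as.integer(params$seed)),
    stalled = isTRUE(obj$stalled), n_levels = k),
    class = "pyramid")
}
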