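#' Density sweep on nested random networks
#'
#' Reproduces the density-robustness experiment: for each seed a nested
#' random network is generated at the base density, thinned to each target
#' density by random link removal, decomposed into a pyramid, and scored
#' against the planted hierarchy. Per-task seeds are derived
#' deterministically from `seed`, so the whole sweep is reproducible.
#'
#' @param densities Numeric vector of target densities, each at most
#'   `target_density`.
#' @param n_seeds Number of networks per density (default 10; the original
#'   protocol used 30).
#' @param z_threshold Z-score threshold for the pyramid builds (default 0).
#' @param seed Master seed from which per-network seeds are derived.
#' @inheritParams calibrate_probabilities
#' @return A data.frame with one row per density: `density`, `mean_nmi`,
#'   `sd_nmi`, `n_seeds`. The full run configuration is attached as
#'   attribute `config`.
#' @export
run_density_sweep <- function(densities, n_seeds = 10, z_threshold = 0,
                              seed = 1, branching = c(4, 4, 4),
                              leaf_size = 10, target_density = 0.0225,
                              rho = 0.25) {
  if (!length(densities)) stop("'densities' must be non-empty")
  if (any(densities > target_density))
    stop("'densities' must not exceed the base 'target_density'")
  seeds <- seed + seq_len(n_seeds)
  per_net <- vapply(seeds, function(s) {
    gen <- generate_nested_network(branching, leaf_size, target_density,
                                   rho, seed = s)
    vapply(densities, function(d) {
      net <- if (network_density(gen$network) > d)
        thin_to_density(gen$network, d, seed = s) else gen$network
      pyr <- build_pyramid(net, z_threshold = z_threshold, seed = s)
      attr(evaluate_hierarchy(pyr, gen$truth), "mean_nmi")
    }, numeric(1))
  }, numeric(length(densities)))
  per_net <- matrix(per_net, nrow = length(densities))
  out <- data.frame(density = densities,
                    mean_nmi = rowMeans(per_net),
                    sd_nmi = apply(per_net, 1, stats::sd),
                    n_seeds = n_seeds)
  attr(out, "config") <- list(densities = densities, n_seeds = n_seeds,
                              z_threshold = z_threshold, seed = seed,
                              seeds = seeds, branching = branching,
                              leaf_size = leaf_size,
                              target_density = target_density, rho = rho)
  out
}

#' Z-score threshold sweep on nested random networks
#'
#' For each seed a nested random network is generated at the base density
#' and decomposed into a pyramid at every threshold; the recovered
#' hierarchies are scored against the planted truth and the isolated
#' supernodes (singleton modules with no remaining proximity to any other
#' module) are counted across levels.
#'
#' @param thresholds Numeric vector of z-score thresholds.
#' @inheritParams run_density_sweep
#' @return A data.frame with one row per threshold: `z_threshold`,
#'   `mean_nmi`, `sd_nmi`, `mean_isolated`, `n_seeds`; configuration in
#'   attribute `config`.
#' @export
run_threshold_sweep <- function(thresholds, n_seeds = 10, seed = 1,
                                branching = c(4, 4, 4), leaf_size = 10,
                                target_density = 0.0225, rho = 0.25) {
  if (!length(thresholds)) stop("'thresholds' must be non-empty")
  if (any(!is.finite(thresholds))) stop("'thresholds' must be finite")
  seeds <- seed + seq_len(n_seeds)
  res <- lapply(seeds, function(s) {
    gen <- generate_nested_network(branching, leaf_size, target_density,
                                   rho, seed = s)
    t(vapply(thresholds, function(z) {
      pyr <- build_pyramid(gen$network, z_threshold = z, seed = s)
      iso <- sum(vapply(pyr$levels, function(l)
        length(l$module_set$isolated), 0L))
      c(nmi = attr(evaluate_hierarchy(pyr, gen$truth), "mean_nmi"),
        isolated = iso)
    }, numeric(2)))
  })
  nmi <- vapply(res, function(m) m[, "nmi"], numeric(length(thresholds)))
  nmi <- matrix(nmi, nrow = length(thresholds))
  iso <- vapply(res, function(m) m[, "isolated"], numeric(length(thresholds)))
  iso <- matrix(iso, nrow = length(thresholds))
  out <- data.frame(z_threshold = thresholds,
                    mean_nmi = rowMeans(nmi),
                    sd_nmi = apply(nmi, 1, stats::sd),
                    mean_isolated = rowMeans(iso),
                    n_seeds = n_seeds)
  attr(out, "config") <- list(thresholds = thresholds, n_seeds = n_seeds,
                              seed = seed, seeds = seeds,
                              branching = branching, leaf_size = leaf_size,
                              target_density = target_density, rho = rho)
  out
}
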