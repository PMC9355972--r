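#' Discretize a continuous signal into three levels
#'
#' Classifies per-mutation signal values (replication timing, CCF, ...) as
#' low / middle / high (1/2/3).  Default cut points are the genome-wide
#' empirical tertiles (1/3 and 2/3 quantiles) of the supplied values; ties
#' at a cut point go to the lower level.
#'
#' @param signal Numeric vector; `NA`s propagate.
#' @param cut_points Optional length-2 numeric `(c1, c2)` overriding the
#'   tertiles.
#' @return Integer vector of levels in 1..3 with attribute `cut_points`.
#' @export
#' @examples
#' discretize_levels(1:9)
discretize_levels <- function(signal, cut_points = NULL) {
  if (is.null(cut_points)) {
    obs <- signal[!is.na(signal)]
    if (length(unique(obs)) < 3) {
      abort("signal has fewer than 3 distinct values; levels undefined")
    }
    cut_points <- unname(quantile(obs, c(1 / 3, 2 / 3)))
  }
  stopifnot(length(cut_points) == 2, cut_points[1] <= cut_points[2])
  lev <- 1L + (signal > cut_points[1]) + (signal > cut_points[2])
  structure(as.integer(lev), cut_points = cut_points)
}

#' Shannon entropy of a region's signal levels
#'
#' `E = -sum_l O_l * ln(O_l)` over the three level fractions, with
#' `0 * ln 0 = 0`; bounded in `[0, ln 3]`.
#'
#' @param levels Integer vector of levels in 1..3 (NAs removed).
#' @return Scalar entropy.
#' @export
region_entropy <- function(levels) {
  levels <- levels[!is.na(levels)]
  if (length(levels) == 0) abort("empty region: no levels")
  p <- tabulate(levels, nbins = 3L) / length(levels)
  p <- p[p > 0]
  -sum(p * log(p))
}

#' Entropy permutation test for one mutation set
#'
#' Tests whether a set of mutations is more concordant in a discretized
#' signal than random sets: draws `B` subsets of the same size, uniformly
#' without replacement from all of the genome's mutations, and computes the
#' fraction of null entropies at or below the observed entropy,
#' `p = |{b : E_b <= E_obs}| / B` (exact integer arithmetic, no
#' pseudocount).
#'
#' @param cluster_levels Integer levels of the cluster's mutations.
#' @param genome_levels Integer levels of all the genome's mutations (the
#'   null pool; must be larger than the cluster).
#' @param B Number of permutations (default 10000).
#' @param seed Integer seed; the draw is reproducible given it.
#' @return List with `entropy`, `p_value`, `null_entropies`, `B`, `seed`.
#' @export
permutation_test <- function(cluster_levels, genome_levels, B = 10000L,
                             seed = 1L) {
  if (B < 1) abort("B must be at least 1")
  cluster_levels <- cluster_levels[!is.na(cluster_levels)]
  genome_levels <- genome_levels[!is.na(genome_levels)]
  n_k <- length(cluster_levels)
  if (n_k < 2) abort("cluster must have at least 2 mutations with signal")
  if (length(genome_levels) < n_k) {
    abort("genome pool smaller than the cluster")
  }
  obs <- region_entropy(cluster_levels)
  null <- withr::with_seed(seed, {
    vapply(seq_len(B), function(b) {
      region_entropy(sample(genome_levels, n_k, replace = FALSE))
    }, numeric(1))
  })
  list(entropy = obs, p_value = sum(null <= obs) / B,
       null_entropies = null, B = as.integer(B), seed = as.integer(seed))
}

#' Within-cluster signal concordance for every mutation cluster
#'
#' Runs the entropy permutation test of [permutation_test()] for each
#' mutation cluster of each sample, using the sample's own mutations as the
#' null pool.  The signal is discretized once per sample into genome-wide
#' tertiles (or explicit `cut_points`).  Mutations without a signal value
#' (track gaps) are dropped and counted.
#'
#' @param assignment A `mut_assignment` (or any catalog-shaped tibble with
#'   `cluster_id`) carrying the per-mutation signal.
#' @param signal_col Name of the signal column (default `"signal"`; use
#'   `"ccf"` for evolutionary concordance).
#' @param cut_points Optional explicit level cut points.
#' @param B Permutations per cluster (default 10000).
#' @param seed Integer seed.
#' @return Tibble with one row per (sample, cluster): `n` (mutations with
#'   signal), `n_dropped`, `entropy`, `p_value`, `B`, `seed`.
#' @export
cluster_concordance <- function(assignment, signal_col = "signal",
                                cut_points = NULL, B = 10000L, seed = 1L) {
  x <- tibble::as_tibble(assignment)
  if (!"cluster_id" %in% names(x)) abort("`assignment` has no cluster_id column")
  if (!signal_col %in% names(x)) {
    abort(sprintf("no `%s` column; attach a signal or CCF first", signal_col))
  }
  out <- list()
  for (s in unique(x$sample_id)) {
    xs <- x[x$sample_id == s, ]
    lev <- discretize_levels(xs[[signal_col]], cut_points)
    pool <- lev[!is.na(lev)]
    for (k in sort(unique(xs$cluster_id))) {
      in_k <- xs$cluster_id == k
      lev_k <- lev[in_k]
      dropped <- sum(is.na(lev_k))
      res <- permutation_test(lev_k, pool, B = B,
                              seed = seed + as.integer(k))
      out[[length(out) + 1L]] <- tibble::tibble(
        sample_id = s, cluster_id = k,
        n = sum(!is.na(lev_k)), n_dropped = dropped,
        entropy = res$entropy, p_value = res$p_value,
        B = res$B, seed = res$seed
      )
    }
  }
  dplyr::bind_rows(out)
}
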