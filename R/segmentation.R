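#' Initial equal-count bins along each chromosome
#'
#' Splits each (sample, chromosome) run of coordinate-sorted mutations into
#' consecutive bins of exactly `min_bin_count` mutations; a trailing
#' remainder smaller than `min_bin_count` is merged into the previous bin,
#' and a chromosome with fewer than `min_bin_count` mutations forms a single
#' bin flagged `small`.
#'
#' @param catalog A mutation catalog.
#' @param config A [seg_config()].
#' @return A `mut_segmentation` tibble, one row per bin, with 0-based
#'   half-open catalog indices `start_idx`/`end_idx`, genomic span
#'   `start_pos`/`end_pos`, the mutation count `n` and the 96-channel count
#'   vector in list-column `counts`.
#' @export
initial_bins <- function(catalog, config = seg_config()) {
  catalog <- assert_catalog(catalog)
  config <- as_seg_config(config)
  if (nrow(catalog) == 0) abort("empty catalog")
  groups <- catalog_groups(catalog)
  m <- config$min_bin_count
  pieces <- purrr::pmap(groups, function(sample_id, chrom, start_row, end_row) {
    n <- end_row - start_row + 1L
    if (n < m) {
      sizes <- n
    } else {
      nb <- n %/% m
      sizes <- rep(m, nb)
      sizes[nb] <- sizes[nb] + n %% m
    }
    ends <- start_row - 1L + cumsum(sizes)
    starts <- ends - sizes + 1L
    tibble::tibble(
      sample_id = sample_id, chrom = chrom,
      start_idx = starts - 1L, end_idx = ends,
      n = sizes,
      start_pos = catalog$pos[starts], end_pos = catalog$pos[ends],
      counts = lapply(seq_along(sizes), function(i) {
        count_vector96(catalog$channel[starts[i]:ends[i]])
      }),
      small = sizes < m
    )
  })
  out <- dplyr::bind_rows(pieces)
  out$segment_id <- seq_len(nrow(out)) - 1L
  out <- out[, c("sample_id", "chrom", "segment_id", "start_idx", "end_idx",
                 "n", "start_pos", "end_pos", "small", "counts")]
  attr(out, "config") <- config
  class(out) <- c("mut_segmentation", class(out))
  out
}

#' Similarity score of two neighboring segments
#'
#' The BIC change from merging the two segments: `Sim = BIC(merged
#' segmentation) - BIC(current segmentation)`, which reduces to the merged
#' likelihood term minus the two segments' own likelihood terms minus
#' `lambda1 * ln(N)`.  Negative (or zero) values mean merging does not
#' increase the BIC and the pair is mergeable.
#'
#' @param counts_a,counts_b 96-channel count vectors of the two segments.
#' @param N Chromosome-wide mutation total entering the penalty.
#' @param config A [seg_config()].
#' @return Scalar score.
#' @export
sim_score <- function(counts_a, counts_b, N, config = seg_config()) {
  config <- as_seg_config(config)
  neg2_loglik_mle(counts_a + counts_b) -
    neg2_loglik_mle(counts_a) - neg2_loglik_mle(counts_b) -
    config$lambda1 * log(N)
}

## Greedy neighbor merge on one chromosome. `counts` is a list of bin count
## vectors in genomic order. Returns integer vector mapping each input bin to
## its merged segment (1-based, consecutive).
merge_chromosome <- function(counts, lambda1) {
  tl <- length(counts)
  if (tl == 1L) return(1L)
  N <- sum(vapply(counts, sum, numeric(1)))
  pen <- lambda1 * log(N)
  f <- vapply(counts, neg2_loglik_mle, numeric(1))
  first_bin <- seq_len(tl)   # first original bin of each live segment
  sizes <- rep(1L, tl)       # original bins per live segment
  sims <- vapply(seq_len(tl - 1L), function(i) {
    neg2_loglik_mle(counts[[i]] + counts[[i + 1L]]) - f[i] - f[i + 1L] - pen
  }, numeric(1))
  while (length(counts) > 1L) {
    i <- which.min(sims)  # leftmost among ties
    if (sims[i] > 0) break
    counts[[i]] <- counts[[i]] + counts[[i + 1L]]
    f[i] <- neg2_loglik_mle(counts[[i]])
    sizes[i] <- sizes[i] + sizes[i + 1L]
    counts[[i + 1L]] <- NULL
    f <- f[-(i + 1L)]
    sizes <- sizes[-(i + 1L)]
    first_bin <- first_bin[-(i + 1L)]
    sims <- sims[-i]
    if (i > 1L) {
      sims[i - 1L] <- neg2_loglik_mle(counts[[i - 1L]] + counts[[i]]) -
        f[i - 1L] - f[i] - pen
    }
    if (i <= length(sims)) {
      sims[i] <- neg2_loglik_mle(counts[[i]] + counts[[i + 1L]]) -
        f[i] - f[i + 1L] - pen
    }
  }
  rep(seq_along(sizes), sizes)
}

#' Greedy local merging of neighboring bins
#'
#' Iteratively merges the neighboring pair with the most negative similarity
#' score (ties broken leftmost) until no pair has `Sim <= 0`, independently
#' on every (sample, chromosome).  The per-chromosome BIC never increases
#' and each accepted merge changes it by exactly the pair's score.
#'
#' @param bins A `mut_segmentation` from [initial_bins()].
#' @param catalog The catalog the bins index.
#' @param config A [seg_config()]; defaults to the one stored in `bins`.
#' @return A converged `mut_segmentation`.
#' @export
local_merge <- function(bins, catalog, config = NULL) {
  config <- as_seg_config(config %||% attr(bins, "config"))
  catalog <- assert_catalog(catalog)
  groups <- dplyr::group_split(dplyr::group_by(
    tibble::as_tibble(bins), .data$sample_id, .data$chrom), .keep = TRUE)
  # group_split sorts groups; restore genomic (catalog) order
  groups <- groups[order(vapply(groups, function(g) g$start_idx[1], numeric(1)))]
  pieces <- lapply(groups, function(g) {
    map <- merge_chromosome(g$counts, config$lambda1)
    merged <- lapply(split(seq_len(nrow(g)), map), function(idx) {
      tibble::tibble(
        sample_id = g$sample_id[idx[1]], chrom = g$chrom[idx[1]],
        start_idx = g$start_idx[idx[1]], end_idx = g$end_idx[idx[length(idx)]],
        n = sum(g$n[idx]),
        start_pos = g$start_pos[idx[1]], end_pos = g$end_pos[idx[length(idx)]],
        small = all(g$small[idx]),
        counts = list(Reduce(`+`, g$counts[idx]))
      )
    })
    dplyr::bind_rows(merged[order(vapply(merged, function(m) m$start_idx, numeric(1)))])
  })
  out <- dplyr::bind_rows(pieces)
  out$segment_id <- seq_len(nrow(out)) - 1L
  out <- out[, c("sample_id", "chrom", "segment_id", "start_idx", "end_idx",
                 "n", "start_pos", "end_pos", "small", "counts")]
  attr(out, "config") <- config
  class(out) <- c("mut_segmentation", class(out))
  out
}

#' Segment a mutation catalog
#'
#' Runs [initial_bins()] followed by [local_merge()]: each chromosome's
#' coordinate-sorted mutations are binned by count and neighboring bins with
#' similar 96-channel spectra are greedily merged under the modified BIC.
#' The result is a partition of each chromosome's mutations into contiguous
#' "mutation segments" with homogeneous trinucleotide spectra.
#'
#' @param catalog A mutation catalog (or data frame coercible to one).
#' @param config A [seg_config()].
#' @return A `mut_segmentation` tibble; see [initial_bins()] for columns.
#' @export
#' @examples
#' H <- toy_signature_matrix()
#' sim <- simulate_catalog(
#'   list(region_spec(n = 300, exposures = c(1, 0, 0, 0)),
#'        region_spec(n = 300, exposures = c(0, 1, 0, 0))),
#'   H, seed = 1)
#' seg <- segment_catalog(sim$catalog)
#' nrow(seg)
segment_catalog <- function(catalog, config = seg_config()) {
  catalog <- assert_catalog(catalog)
  local_merge(initial_bins(catalog, config), catalog, config)
}

#' @export
print.mut_segmentation <- function(x, ...) {
  cat(sprintf("# Mutation segmentation: %d segment(s), %d mutation(s)\n",
              nrow(x), sum(x$n)))
  NextMethod()
  invisible(x)
}

## Recompute the per-(sample, chrom) segmentation BIC from scratch.
segmentation_bic_by_chrom <- function(segmentation, config = NULL) {
  config <- as_seg_config(config %||% attr(segmentation, "config"))
  x <- tibble::as_tibble(segmentation)
  dplyr::summarise(
    dplyr::group_by(x, .data$sample_id, .data$chrom),
    T = dplyr::n(), N = sum(.data$n),
    bic = segmentation_bic(.data$counts, config),
    .groups = "drop"
  )
}
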