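#' Detect kataegis events
#'
#' A kataegic event is a maximal run of at least `min_run` consecutive
#' mutations on one chromosome in which every successive pair is separated
#' by fewer than `max_dist` bp (strict inequality).  Samples with more than
#' `max_mutations` SNVs are hypermutated and skipped (reported in attribute
#' `skipped_samples`).
#'
#' @param catalog A mutation catalog.
#' @param min_run Minimum run length (default 6).
#' @param max_dist Maximum inter-mutation distance in bp, exclusive
#'   (default 1000).
#' @param max_mutations Hypermutation cap per sample (default 30000).
#' @return Tibble of events: `sample_id`, `chrom`, `start`, `end` (positions
#'   of the first/last member), `size`, and 1-based catalog row range
#'   `start_row`/`end_row`.
#' @export
detect_kataegis <- function(catalog, min_run = 6L, max_dist = 1000L,
                            max_mutations = 30000L) {
  catalog <- assert_catalog(catalog)
  counts <- table(catalog$sample_id)
  skipped <- names(counts)[counts > max_mutations]
  groups <- catalog_groups(catalog)
  groups <- groups[!groups$sample_id %in% skipped, , drop = FALSE]
  out <- purrr::pmap(groups, function(sample_id, chrom, start_row, end_row) {
    pos <- catalog$pos[start_row:end_row]
    if (length(pos) < min_run) return(NULL)
    close <- diff(pos) < max_dist
    r <- rle(close)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    keep <- r$values & r$lengths >= (min_run - 1L)
    if (!any(keep)) return(NULL)
    tibble::tibble(
      sample_id = sample_id, chrom = chrom,
      start = pos[starts[keep]], end = pos[ends[keep] + 1L],
      size = r$lengths[keep] + 1L,
      start_row = start_row - 1L + starts[keep],
      end_row = start_row - 1L + ends[keep] + 1L
    )
  })
  out <- dplyr::bind_rows(out)
  attr(out, "skipped_samples") <- skipped
  out
}

#' Per-signature Fisher enrichment of kataegic events
#'
#' For each signature observed in an event, a one-sided (enrichment)
#' Fisher's exact test on the 2x2 table of (event vs rest of the sample) by
#' (that signature vs all others), using the per-mutation signature
#' assignments.  An event may carry two or more enriched signatures.
#'
#' @param events Tibble from [detect_kataegis()].
#' @param assignment A `mut_assignment` covering the events' samples.
#' @param alpha Enrichment call threshold on the p-value (default 0.05).
#' @return Long tibble: one row per (event, observed signature) with the
#'   member count `k`, sample-wide count `n_sample`, `p_value` and
#'   `enriched`.
#' @export
kataegis_enrichment <- function(events, assignment, alpha = 0.05) {
  x <- tibble::as_tibble(assignment)
  out <- list()
  for (i in seq_len(nrow(events))) {
    ev <- events[i, ]
    xs <- x[x$sample_id == ev$sample_id, ]
    if (nrow(xs) == 0) {
      abort(sprintf("sample %s of event %d absent from assignments",
                    ev$sample_id, i))
    }
    rows <- ev$start_row:ev$end_row
    lab_event <- x$best_signature[rows]
    lab_event <- lab_event[!is.na(lab_event)]
    lab_sample <- xs$best_signature[!is.na(xs$best_signature)]
    n_event <- length(lab_event)
    n_rest <- length(lab_sample) - n_event
    for (sig in sort(unique(lab_event))) {
      a <- sum(lab_event == sig)
      c_ <- sum(lab_sample == sig) - a
      tab <- matrix(c(a, n_event - a, c_, n_rest - c_), nrow = 2)
      p <- fisher.test(tab, alternative = "greater")$p.value
      out[[length(out) + 1L]] <- tibble::tibble(
        sample_id = ev$sample_id, chrom = ev$chrom,
        start = ev$start, end = ev$end, size = ev$size,
        signature = sig, k = a, n_event = n_event,
        n_sample = length(lab_sample),
        p_value = p, enriched = p < alpha
      )
    }
  }
  dplyr::bind_rows(out)
}

#' Pairwise CCF discordance of signatures (Kolmogorov-Smirnov)
#'
#' Within each sample, every pair of signatures with at least
#' `min_per_signature` assigned mutations is compared by a two-sided
#' two-sample KS test on the mutations' cancer cell fractions, under the
#' null that the two signatures' CCF values share one distribution.
#' P-values are Benjamini-Hochberg adjusted across all pairs of all
#' samples; pairs with `fdr_q < alpha` are reported discordant, and the
#' signature with the higher median CCF is labeled the earlier one.
#'
#' @param assignment A `mut_assignment` whose catalog carries a `ccf`
#'   column.
#' @param min_per_signature Minimum assigned mutations per signature
#'   (default 10).
#' @param alpha FDR threshold (default 0.05).
#' @return Tibble: `sample_id`, `sig_a`, `sig_b`, `n_a`, `n_b`,
#'   `statistic` (D), `p_value`, `fdr_q`, `discordant`, `earlier`.  Empty
#'   (zero-row) with a message when no sample has two eligible signatures.
#' @export
ccf_pair_discordance <- function(assignment, min_per_signature = 10L,
                                 alpha = 0.05) {
  x <- tibble::as_tibble(assignment)
  if (!"ccf" %in% names(x)) abort("assignment carries no `ccf` column")
  x <- x[!is.na(x$ccf) & !is.na(x$best_signature), ]
  out <- list()
  for (s in unique(x$sample_id)) {
    xs <- x[x$sample_id == s, ]
    tab <- table(xs$best_signature)
    sigs <- sort(names(tab)[tab >= min_per_signature])
    if (length(sigs) < 2) next
    for (ia in seq_len(length(sigs) - 1L)) {
      for (ib in seq((ia + 1L), length(sigs))) {
        ccf_a <- xs$ccf[xs$best_signature == sigs[ia]]
        ccf_b <- xs$ccf[xs$best_signature == sigs[ib]]
        kt <- suppressWarnings(ks.test(ccf_a, ccf_b))
        out[[length(out) + 1L]] <- tibble::tibble(
          sample_id = s, sig_a = sigs[ia], sig_b = sigs[ib],
          n_a = length(ccf_a), n_b = length(ccf_b),
          statistic = unname(kt$statistic), p_value = kt$p.value,
          median_a = median(ccf_a), median_b = median(ccf_b)
        )
      }
    }
  }
  if (!length(out)) {
    message("no sample has two signatures meeting min_per_signature")
    return(tibble::tibble(
      sample_id = character(), sig_a = character(), sig_b = character(),
      n_a = integer(), n_b = integer(), statistic = numeric(),
      p_value = numeric(), fdr_q = numeric(), discordant = logical(),
      earlier = character()
    ))
  }
  res <- dplyr::bind_rows(out)
  res$fdr_q <- p.adjust(res$p_value, method = "BH")
  res$discordant <- res$fdr_q < alpha
  res$earlier <- ifelse(res$median_a >= res$median_b, res$sig_a, res$sig_b)
  dplyr::select(res, -dplyr::all_of(c("median_a", "median_b")))
}
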