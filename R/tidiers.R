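#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a segmentation into one row per segment
#'
#' @param x A `mut_segmentation`.
#' @param ... Unused.
#' @return Tibble without the list-column of counts.
#' @export
tidy.mut_segmentation <- function(x, ...) {
  dplyr::select(tibble::as_tibble(x), -dplyr::any_of("counts"))
}

#' One-row-per-chromosome segmentation summary
#'
#' @param x A `mut_segmentation`.
#' @param ... Unused.
#' @return Tibble with segment count `T`, mutation count `N` and the
#'   recomputed BIC per (sample, chromosome).
#' @export
glance.mut_segmentation <- function(x, ...) {
  segmentation_bic_by_chrom(x)
}

#' One-row-per-sample clustering summary
#'
#' @param x A `mut_clustering`.
#' @param ... Unused.
#' @return Tibble with cluster count `K`, mutation count `N` and the
#'   recomputed clustering BIC per sample.
#' @export
glance.mut_clustering <- function(x, ...) {
  clustering_bic_by_sample(x)
}

#' Tidy per-mutation assignments
#'
#' @param x A `mut_assignment`.
#' @param ... Unused.
#' @return Tibble of coordinates, channel, segment/cluster ids, best
#'   signature and its posterior (posterior columns are kept in the
#'   original object).
#' @export
tidy.mut_assignment <- function(x, ...) {
  keep <- intersect(c("sample_id", "chrom", "pos", "ref", "alt", "channel",
                      "segment_id", "cluster_id", "best_signature",
                      "max_posterior", "unassigned", "ccf", "signal"),
                    names(x))
  tibble::as_tibble(x)[, keep]
}

#' Per-sample assignment summary
#'
#' @param x A `mut_assignment`.
#' @param ... Unused.
#' @return Tibble with mutation counts, unassigned counts and the mean
#'   maximum posterior per sample.
#' @export
glance.mut_assignment <- function(x, ...) {
  dplyr::summarise(
    dplyr::group_by(tibble::as_tibble(x), .data$sample_id),
    n = dplyr::n(),
    n_unassigned = sum(.data$unassigned),
    mean_max_posterior = mean(.data$max_posterior, na.rm = TRUE),
    n_clusters = dplyr::n_distinct(.data$cluster_id),
    .groups = "drop"
  )
}

#' Exposure table of an assignment
#'
#' @param assignment A `mut_assignment`.
#' @return Tidy tibble (sample_id, unit_id, granularity, signature,
#'   exposure); `unit_id` is the cluster or segment id, `NA` at sample
#'   granularity.
#' @export
exposures <- function(assignment) {
  ex <- attr(assignment, "exposures")
  if (is.null(ex)) abort("object carries no exposures attribute")
  ex
}
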