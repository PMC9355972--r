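#' Construct a mutation catalog from a data frame
#'
#' A mutation catalog is a tibble with one row per somatic SNV, sorted by
#' `(sample_id, chrom, pos)`, carrying at minimum the columns `sample_id`,
#' `chrom`, `pos` (1-based), `ref`, `alt` and the 0-based SBS-96 `channel`.
#' Optional columns `ccf` (cancer cell fraction in \[0, 1\]) and `signal`
#' (an external per-mutation value such as replication timing) enable the
#' concordance and clonality analyses.
#'
#' Rows duplicated on `(sample_id, chrom, pos, alt)` are dropped with a
#' warning; unsorted input is sorted silently.
#'
#' @param x A data frame with the columns above.  If `channel` is absent but
#'   a `context` column (reference-strand trinucleotide) is present, channels
#'   are computed with [encode_context()].
#' @return A `mut_catalog` tibble.
#' @export
as_mut_catalog <- function(x) {
  x <- tibble::as_tibble(x)
  if (!"sample_id" %in% names(x)) x$sample_id <- "sample1"
  need <- c("chrom", "pos", "ref", "alt")
  miss <- setdiff(need, names(x))
  if (length(miss)) {
    abort(paste0("catalog is missing column(s): ", paste(miss, collapse = ", ")))
  }
  if (!"channel" %in% names(x)) {
    if (!"context" %in% names(x)) {
      abort("catalog needs either a `channel` or a `context` column")
    }
    x$channel <- encode_context(x$context, x$ref, x$alt)
  }
  x$pos <- as.integer(x$pos)
  x$channel <- as.integer(x$channel)
  if (any(x$ref == x$alt)) abort("invalid record: ref == alt")
  if (any(x$channel < 0L | x$channel > 95L)) abort("channel out of 0..95")
  x <- dplyr::arrange(x, .data$sample_id, .data$chrom, .data$pos)
  dup <- duplicated(x[, c("sample_id", "chrom", "pos", "alt")])
  if (any(dup)) {
    warn(sprintf("dropping %d duplicated record(s)", sum(dup)))
    x <- x[!dup, , drop = FALSE]
  }
  if (nrow(x) == 0) abort("zero usable records in catalog")
  class(x) <- c("mut_catalog", class(x))
  x
}

is_mut_catalog <- function(x) inherits(x, "mut_catalog")

assert_catalog <- function(x) {
  if (!is_mut_catalog(x)) x <- as_mut_catalog(x)
  x
}

#' @export
print.mut_catalog <- function(x, ...) {
  n_samp <- dplyr::n_distinct(x$sample_id)
  cat(sprintf("# Mutation catalog: %d SNVs, %d sample(s), %d chromosome(s)\n",
              nrow(x), n_samp, dplyr::n_distinct(x$chrom)))
  NextMethod()
  invisible(x)
}

## Per-(sample, chrom) run-length view used by segmentation and kataegis;
## relies on the catalog sort order.
catalog_groups <- function(catalog) {
  key <- paste(catalog$sample_id, catalog$chrom, sep = "\r")
  r <- rle(key)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  tibble::tibble(
    sample_id = catalog$sample_id[starts],
    chrom = catalog$chrom[starts],
    start_row = starts,
    end_row = ends
  )
}
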