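#' @importFrom rlang .data abort warn %||%
#' @importFrom stats quantile rbeta rgeom setNames median fisher.test ks.test p.adjust runif
#' @importFrom utils head tail
NULL

BASES <- c("A", "C", "G", "T")
SUB_CLASSES <- c("C>A", "C>G", "C>T", "T>A", "T>C", "T>G")

#' Canonical SBS-96 channel labels
#'
#' The 96 single-base-substitution channels in canonical COSMIC order: the six
#' pyrimidine-reference substitution classes C>A, C>G, C>T, T>A, T>C, T>G, and
#' within each class the 16 flanking-base pairs ordered A, C, G, T by the 5'
#' base first, then the 3' base.  Channel indices used throughout the package
#' are 0-based (0..95) so that they are stable across files and languages.
#'
#' @return Character vector of length 96, e.g. `"A[C>A]A"`, in channel order.
#' @export
#' @examples
#' sbs96_channels()[1:4]
sbs96_channels <- function() {
  unlist(lapply(SUB_CLASSES, function(sub) {
    ref <- substr(sub, 1, 1)
    as.vector(t(outer(BASES, BASES, function(p5, p3) {
      paste0(p5, "[", sub, "]", p3)
    })))
  }), use.names = FALSE)
}

revcomp <- function(x) {
  chartr("ACGT", "TGCA", vapply(strsplit(x, NULL), function(s) {
    paste(rev(s), collapse = "")
  }, character(1)))
}

comp_base <- function(x) chartr("ACGT", "TGCA", x)

#' Encode a trinucleotide substitution as an SBS-96 channel
#'
#' Maps a mutation given by its reference trinucleotide context and the
#' substituted base to its 0-based channel index in the canonical ordering
#' (see [sbs96_channels()]).  Purine-reference mutations are collapsed onto
#' the pyrimidine strand by reverse complement, so e.g. `TGT` with `G>T` is
#' the same channel as `ACA` with `C>A`.
#'
#' @param trinucleotide Character vector of 3-base contexts (middle base =
#'   `ref`), reference-strand orientation.
#' @param ref,alt Character vectors of single bases (A/C/G/T), recycled to the
#'   length of `trinucleotide`.
#' @return Integer vector of channel indices in 0..95.
#' @export
#' @examples
#' encode_context("ACA", "C", "A")  # 0
#' encode_context("TGT", "G", "T")  # 0, reverse complement of the above
encode_context <- function(trinucleotide, ref, alt) {
  trinucleotide <- toupper(trinucleotide)
  ref <- toupper(ref)
  alt <- toupper(alt)
  n <- length(trinucleotide)
  ref <- rep_len(ref, n)
  alt <- rep_len(alt, n)
  if (any(nchar(trinucleotide) != 3L)) {
    abort("`trinucleotide` must be 3-base strings.")
  }
  bad_base <- !grepl("^[ACGT]{3}$", trinucleotide) |
    !(ref %in% BASES) | !(alt %in% BASES)
  if (any(bad_base)) {
    abort(sprintf(
      "context unresolvable: non-ACGT base in %d record(s) (first: %s %s>%s)",
      sum(bad_base), trinucleotide[bad_base][1], ref[bad_base][1],
      alt[bad_base][1]
    ), class = "sigseg_context_error")
  }
  if (any(ref == alt)) {
    abort("invalid record: ref == alt", class = "sigseg_record_error")
  }
  if (any(substr(trinucleotide, 2, 2) != ref)) {
    abort("middle base of `trinucleotide` must equal `ref`")
  }
  pur <- ref %in% c("A", "G")
  if (any(pur)) {
    trinucleotide[pur] <- revcomp(trinucleotide[pur])
    ref[pur] <- comp_base(ref[pur])
    alt[pur] <- comp_base(alt[pur])
  }
  sub_idx <- match(paste0(ref, ">", alt), SUB_CLASSES) - 1L
  p5 <- match(substr(trinucleotide, 1, 1), BASES) - 1L
  p3 <- match(substr(trinucleotide, 3, 3), BASES) - 1L
  sub_idx * 16L + p5 * 4L + p3
}

#' Decode SBS-96 channel indices
#'
#' Inverse of [encode_context()] on the pyrimidine strand.
#'
#' @param channel Integer vector in 0..95.
#' @return Tibble with columns `channel`, `context` (pyrimidine-strand
#'   trinucleotide), `ref`, `alt`, `label`.
#' @export
decode_channel <- function(channel) {
  stopifnot(all(channel >= 0L & channel <= 95L))
  lab <- sbs96_channels()[channel + 1L]
  tibble::tibble(
    channel = as.integer(channel),
    context = paste0(substr(lab, 1, 1), substr(lab, 3, 3), substr(lab, 7, 7)),
    ref = substr(lab, 3, 3),
    alt = substr(lab, 5, 5),
    label = lab
  )
}

#' Tabulate channels into a 96-count vector
#'
#' @param channel Integer vector of 0-based channel indices.
#' @return Integer vector of length 96 of per-channel counts.
#' @export
count_vector96 <- function(channel) {
  stopifnot(all(channel >= 0L & channel <= 95L))
  tabulate(channel + 1L, nbins = 96L)
}

#' Model configuration for segmentation and clustering
#'
#' Holds the tuning parameters of the modified BIC objectives: `lambda1`
#' scales the per-segment penalty in segmentation, `lambda2` the per-cluster
#' penalty in clustering, and `min_bin_count` is the number of mutations per
#' initial bin.  Defaults are lambda1 = 5, lambda2 = 5 and 30 mutations per
#' bin.  Natural logarithms are used throughout.
#'
#' @param lambda1,lambda2 Positive reals; BIC penalty multipliers.
#' @param min_bin_count Positive integer; mutations per initial bin.
#' @return A `sigseg_config` list.
#' @export
seg_config <- function(lambda1 = 5, lambda2 = 5, min_bin_count = 30L) {
  stopifnot(is.numeric(lambda1), lambda1 > 0,
            is.numeric(lambda2), lambda2 > 0,
            is.numeric(min_bin_count), min_bin_count >= 1)
  structure(
    list(lambda1 = lambda1, lambda2 = lambda2,
         min_bin_count = as.integer(min_bin_count)),
    class = "sigseg_config"
  )
}

as_seg_config <- function(config) {
  if (inherits(config, "sigseg_config")) return(config)
  if (is.null(config)) return(seg_config())
  do.call(seg_config, as.list(config))
}

#' Multinomial maximum-likelihood profile of a count vector
#'
#' @param counts Nonnegative integer vector (usually length 96) with at least
#'   one positive entry.
#' @return Numeric vector of the same length summing to 1.
#' @export
mle_profile <- function(counts) {
  n <- sum(counts)
  if (n <= 0) abort("empty segment: counts sum to zero")
  counts / n
}

#' Twice the negative multinomial log-likelihood
#'
#' Computes `-2 * sum_i counts_i * ln(q_i)` with the convention
#' `0 * ln 0 = 0`, so zero-count channels never contribute.  If a channel has
#' positive count where `q` is zero the value is `+Inf` and the result
#' carries attribute `zero_support = TRUE` (flagged, not an error).
#'
#' @param counts Nonnegative count vector.
#' @param q Probability vector of the same length (sums to 1).
#' @return Scalar; nonnegative when `q = mle_profile(counts)`.
#' @export
neg2_loglik <- function(counts, q) {
  pos <- counts > 0
  if (any(pos & q <= 0)) {
    return(structure(Inf, zero_support = TRUE))
  }
  -2 * sum(counts[pos] * log(q[pos]))
}

## -2 log-likelihood of counts at their own MLE; the likelihood term every
## BIC below is built from.
neg2_loglik_mle <- function(counts) {
  pos <- counts > 0
  n <- sum(counts)
  -2 * sum(counts[pos] * log(counts[pos] / n))
}

#' Modified BIC of a segmentation
#'
#' `BIC(S) = sum_t -2 log L(S_t) + lambda1 * T * ln(N)` where each segment's
#' likelihood is evaluated at its own multinomial MLE and `N` is the total
#' mutation count over the segments (the per-chromosome total in the
#' segmentation algorithm).
#'
#' @param segments List of count vectors, one per segment, each nonempty.
#' @param config A [seg_config()].
#' @return Scalar BIC value.
#' @export
segmentation_bic <- function(segments, config = seg_config()) {
  config <- as_seg_config(config)
  if (length(segments) == 0) abort("empty segment list")
  ns <- vapply(segments, sum, numeric(1))
  if (any(ns <= 0)) abort("empty segment: counts sum to zero")
  N <- sum(ns)
  sum(vapply(segments, neg2_loglik_mle, numeric(1))) +
    config$lambda1 * length(segments) * log(N)
}

#' Modified BIC of a clustering
#'
#' Same form as [segmentation_bic()] with `K` pooled clusters and penalty
#' multiplier `lambda2`; `N` is the genome-wide mutation total.
#'
#' @param clusters List of pooled count vectors, one per cluster.
#' @param config A [seg_config()].
#' @return Scalar BIC value.
#' @export
clustering_bic <- function(clusters, config = seg_config()) {
  config <- as_seg_config(config)
  if (length(clusters) == 0) abort("empty cluster list")
  ns <- vapply(clusters, sum, numeric(1))
  if (any(ns <= 0)) abort("empty cluster: counts sum to zero")
  N <- sum(ns)
  sum(vapply(clusters, neg2_loglik_mle, numeric(1))) +
    config$lambda2 * length(clusters) * log(N)
}

#' NpCpG C>T probability mass per signature
#'
#' For each signature, the summed probability of the 16 C>T channels whose 3'
#' flanking base is G (i.e. C>T transitions at CpG dinucleotides, any 5'
#' base).  This is the quantity whose value distinguishes the age-related
#' clock-like signature from other signatures that share the same nucleotide
#' change.
#'
#' @param H A signature matrix as returned by [read_signature_matrix()]
#'   (V x 96, rows summing to 1, columns in canonical channel order).
#' @return Named numeric vector of per-signature fractions in \[0, 1\].
#' @export
npcpg_fraction <- function(H) {
  validate_signature_matrix(H)
  lab <- sbs96_channels()
  sel <- grepl("\\[C>T\\]G$", lab)
  rowSums(H[, sel, drop = FALSE])
}
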