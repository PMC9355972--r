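#' Greedy BIC clustering of mutation segments
#'
#' Starting from one cluster per segment, repeatedly evaluates the BIC
#' change of merging every unordered cluster pair and merges the pair with
#' the largest reduction, stopping when the best change is positive.
#' Merged clusters need not be genomically adjacent and (by default)
#' clustering crosses chromosome boundaries within each sample; the penalty
#' uses the sample's genome-wide mutation total and multiplier `lambda2`.
#' Ties are broken toward the lexicographically lowest cluster-id pair, so
#' runs are deterministic and invariant to segment input order.
#'
#' Cluster ids are renumbered 0..K-1 by genomic position of each cluster's
#' first segment.
#'
#' @param segmentation A `mut_segmentation` from [segment_catalog()].
#' @param config A [seg_config()]; defaults to the one stored in the
#'   segmentation.
#' @param per_chromosome If `TRUE`, cluster each chromosome separately
#'   (genome-wide is the default).
#' @return A `mut_clustering` tibble: the segmentation with a `cluster_id`
#'   column.  Attribute `clusters` holds the per-cluster summary (member
#'   count `s_k`, pooled mutation count `N_k`, pooled `counts`).
#' @export
cluster_segments <- function(segmentation, config = NULL,
                             per_chromosome = FALSE) {
  config <- as_seg_config(config %||% attr(segmentation, "config"))
  if (nrow(segmentation) == 0) abort("empty segmentation")
  x <- tibble::as_tibble(segmentation)
  key <- if (per_chromosome) paste(x$sample_id, x$chrom, sep = "\r") else x$sample_id
  x$cluster_id <- NA_integer_
  for (k in unique(key)) {
    rows <- which(key == k)
    # greedy_cluster labels clusters by their first (genomically lowest)
    # member, so 0-based ids follow genomic order directly
    memb <- greedy_cluster(x$counts[rows], config$lambda2)
    x$cluster_id[rows] <- memb - 1L
  }
  out <- x
  attr(out, "config") <- config
  attr(out, "clusters") <- dplyr::summarise(
    dplyr::group_by(out, .data$sample_id, .data$cluster_id),
    s_k = dplyr::n(), N_k = sum(.data$n),
    counts = list(Reduce(`+`, .data$counts)),
    .groups = "drop"
  )
  class(out) <- c("mut_clustering", "mut_segmentation", class(out))
  out
}

## Greedy pairwise merging of count vectors under the clustering BIC.
## Returns an integer membership vector over the input segments; cluster
## labels are in order of each cluster's first (lowest-index) member, which
## for genomically ordered segments is genomic order.
greedy_cluster <- function(counts, lambda2) {
  tl <- length(counts)
  if (tl == 1L) return(1L)
  N <- sum(vapply(counts, sum, numeric(1)))
  pen <- lambda2 * log(N)
  f <- vapply(counts, neg2_loglik_mle, numeric(1))
  members <- as.list(seq_len(tl))
  pair_delta <- function(a, b) {
    neg2_loglik_mle(counts[[a]] + counts[[b]]) - f[a] - f[b] - pen
  }
  K <- tl
  D <- matrix(NA_real_, K, K)
  for (a in seq_len(K - 1L)) {
    for (b in seq((a + 1L), K)) D[a, b] <- pair_delta(a, b)
  }
  while (K > 1L) {
    best <- min(D[upper.tri(D)])
    if (best > 0) break
    hits <- which(D == best & upper.tri(D), arr.ind = TRUE)
    # lexicographically lowest (a, b) among equal-best merges
    hits <- hits[order(hits[, 1L], hits[, 2L]), , drop = FALSE]
    a <- hits[1L, 1L]; b <- hits[1L, 2L]
    counts[[a]] <- counts[[a]] + counts[[b]]
    f[a] <- neg2_loglik_mle(counts[[a]])
    members[[a]] <- c(members[[a]], members[[b]])
    counts[[b]] <- NULL
    members[[b]] <- NULL
    f <- f[-b]
    D <- D[-b, -b, drop = FALSE]
    K <- K - 1L
    if (K == 1L) break
    for (o in seq_len(K)) {
      if (o == a) next
      lo <- min(o, a); hi <- max(o, a)
      D[lo, hi] <- pair_delta(lo, hi)
    }
  }
  # order clusters by their first member's index
  members <- members[order(vapply(members, min, numeric(1)))]
  memb <- integer(tl)
  for (i in seq_along(members)) memb[members[[i]]] <- i
  memb
}

#' Per-cluster pooled signature-space profiles
#'
#' @param clustering A `mut_clustering`.
#' @return Tibble with `sample_id`, `cluster_id`, `s_k`, `N_k` and a
#'   list-column `profile` of pooled MLE profiles (each summing to 1); the
#'   K x 96 profile matrix of one sample can be had with
#'   `do.call(rbind, out$profile)`.
#' @export
cluster_profiles <- function(clustering) {
  cl <- attr(clustering, "clusters")
  if (is.null(cl)) abort("not a mut_clustering (missing clusters attribute)")
  cl$profile <- lapply(cl$counts, mle_profile)
  cl[, c("sample_id", "cluster_id", "s_k", "N_k", "profile")]
}

#' @export
print.mut_clustering <- function(x, ...) {
  cl <- attr(x, "clusters")
  cat(sprintf("# Mutation clustering: %d cluster(s) over %d segment(s)\n",
              nrow(cl), nrow(x)))
  NextMethod()
  invisible(x)
}

## Recompute the per-sample clustering BIC from scratch.
clustering_bic_by_sample <- function(clustering, config = NULL) {
  config <- as_seg_config(config %||% attr(clustering, "config"))
  cl <- attr(clustering, "clusters")
  dplyr::summarise(
    dplyr::group_by(cl, .data$sample_id),
    K = dplyr::n(), N = sum(.data$N_k),
    bic = clustering_bic(.data$counts, config),
    .groups = "drop"
  )
}
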