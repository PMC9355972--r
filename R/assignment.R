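#' Estimate signature exposures for a 96-channel count vector
#'
#' Refits the mixture weights (exposures) of known signatures to an observed
#' count vector.  The default `"em"` method maximizes the multinomial
#' likelihood of the counts under the mixture `sum_v d_v * h_v` by
#' expectation-maximization from a uniform start, stopping when the largest
#' absolute weight change falls below `tol` (default 1e-8) or after
#' `max_iter` iterations; the log-likelihood is non-decreasing across
#' iterations.  The `"nnls"` method regresses the normalized count vector on
#' the signature profiles by Lawson-Hanson non-negative least squares
#' (`pracma::lsqnonneg`) and renormalizes the weights to sum 1.  Both are
#' deterministic.
#'
#' Channels with positive counts where every signature has zero probability
#' cannot be explained by the model; their counts are excluded from the fit
#' and reported in attribute `excluded_counts`.
#'
#' @param counts 96-channel count vector with positive sum.
#' @param H Signature matrix (V x 96, rows sum to 1).
#' @param method `"em"` (default) or `"nnls"`.
#' @param tol,max_iter EM convergence controls.
#' @param min_exposure Optional threshold: exposures below it are zeroed and
#'   the rest renormalized (the deconstructSigs-style discard; default 0, no
#'   thresholding).
#' @return Named numeric vector `d` of length V, nonnegative, summing to 1.
#'   EM results carry attributes `iterations` and `loglik_trace`.
#' @export
#' @examples
#' H <- toy_signature_matrix()
#' counts <- round(2000 * (0.7 * H[1, ] + 0.3 * H[2, ]))
#' round(estimate_exposures(counts, H), 3)
estimate_exposures <- function(counts, H, method = c("em", "nnls"),
                               tol = 1e-8, max_iter = 10000L,
                               min_exposure = 0) {
  method <- match.arg(method)
  H <- validate_signature_matrix(H)
  V <- nrow(H)
  if (sum(counts) <= 0) abort("empty cluster: counts sum to zero")
  unexplained <- counts > 0 & colSums(H) == 0
  excluded <- sum(counts[unexplained])
  if (excluded > 0) {
    warn(sprintf("%d mutation(s) on channels no signature can produce; excluded from fit",
                 excluded))
    counts <- replace(counts, unexplained, 0)
  }
  if (method == "em") {
    d <- rep(1 / V, V)
    act <- which(counts > 0)
    w <- counts[act]
    M <- H[, act, drop = FALSE]
    n <- sum(w)
    ll <- numeric(0)
    iter <- 0L
    repeat {
      iter <- iter + 1L
      t_vc <- d * M                      # V x C, columns recycle d
      denom <- colSums(t_vc)
      ll <- c(ll, sum(w * log(denom)))
      d_new <- as.vector(t_vc %*% (w / denom)) / n
      delta <- max(abs(d_new - d))
      d <- d_new
      if (delta < tol || iter >= max_iter) break
    }
    d <- d / sum(d)
    names(d) <- rownames(H)
    d <- apply_min_exposure(d, min_exposure)
    attr(d, "iterations") <- iter
    attr(d, "loglik_trace") <- ll
    d
  } else {
    fit <- pracma::lsqnonneg(t(H), counts / sum(counts))
    d <- fit$x
    if (sum(d) <= 0) abort("NNLS returned all-zero exposures")
    d <- d / sum(d)
    names(d) <- rownames(H)
    apply_min_exposure(d, min_exposure)
  }
}

apply_min_exposure <- function(d, min_exposure) {
  if (min_exposure > 0) {
    d[d < min_exposure] <- 0
    if (sum(d) <= 0) abort("min_exposure removed every signature")
    d <- d / sum(d)
  }
  d
}

#' Posterior signature probabilities for channels under fixed exposures
#'
#' For a mutation of channel `c` in a region with exposures `d`, the
#' posterior probability of signature `v` is
#' `h_vc * d_v / sum_w h_wc * d_w`.  Rows whose denominator underflows
#' (below 1e-300) are flagged unassigned rather than given a fabricated
#' label.
#'
#' @param channel Integer vector of 0-based channels.
#' @param d Exposure vector (length V, sums to 1).
#' @param H Signature matrix (V x 96).
#' @return List with `posterior` (length(channel) x V matrix),
#'   `best` (integer argmax per row, ties to the lowest signature index,
#'   `NA` when flagged) and `unassigned` (logical).
#' @export
posterior_assign <- function(channel, d, H) {
  H <- validate_signature_matrix(H)
  stopifnot(length(d) == nrow(H))
  num <- t(d * H[, channel + 1L, drop = FALSE])  # n x V
  denom <- rowSums(num)
  unassigned <- denom < 1e-300
  post <- num / ifelse(unassigned, NA_real_, denom)
  best <- ifelse(unassigned, NA_integer_, max.col(replace(post, is.na(post), -1),
                                                  ties.method = "first"))
  colnames(post) <- rownames(H)
  list(posterior = post, best = as.integer(best), unassigned = unassigned)
}

#' Assign every mutation to its maximum-posterior signature
#'
#' Estimates signature exposures for each unit (mutation cluster by
#' default) and assigns each mutation to the signature maximizing
#' `h_vc * d_rv / sum_w h_wc * d_rw`, where `d_r` are the unit's exposures
#' and `c` the mutation's channel.  `granularity` selects the unit on which
#' exposures are estimated: `"cluster"` (the method's intended resolution),
#' `"segment"`, or `"sample"` (the whole genome, the conventional refit).
#'
#' @param catalog The mutation catalog.
#' @param clustering A `mut_clustering` of the same catalog (may be a bare
#'   `mut_segmentation` when `granularity = "segment"` or `"sample"`).
#' @param H Signature matrix.
#' @param method Exposure method, `"em"` or `"nnls"`.
#' @param granularity `"cluster"`, `"segment"` or `"sample"`.
#' @param min_exposure Passed to [estimate_exposures()].
#' @return A `mut_assignment` tibble: the catalog plus `segment_id`,
#'   `cluster_id`, posterior columns `p_<signature>`, `best_signature`
#'   (character, `NA` when unassigned), `max_posterior` and `unassigned`.
#'   Attribute `exposures` is a tidy tibble (sample_id, unit id, signature,
#'   exposure).
#' @export
assign_signatures <- function(catalog, clustering, H,
                              method = c("em", "nnls"),
                              granularity = c("cluster", "segment", "sample"),
                              min_exposure = 0) {
  method <- match.arg(method)
  granularity <- match.arg(granularity)
  catalog <- assert_catalog(catalog)
  H <- validate_signature_matrix(H)
  segs <- tibble::as_tibble(clustering)
  if (granularity == "cluster" && !"cluster_id" %in% names(segs)) {
    abort("granularity = \"cluster\" needs a mut_clustering; run cluster_segments() first")
  }

  # map each mutation to its segment (pipeline-order contract)
  seg_of <- rep(NA_integer_, nrow(catalog))
  for (i in seq_len(nrow(segs))) {
    seg_of[(segs$start_idx[i] + 1L):segs$end_idx[i]] <- i
  }
  if (anyNA(seg_of)) abort("mutation without a segment: segmentation does not cover the catalog")

  out <- tibble::as_tibble(catalog)
  out$segment_id <- segs$segment_id[seg_of]
  out$cluster_id <- if ("cluster_id" %in% names(segs)) {
    segs$cluster_id[seg_of]
  } else NA_integer_

  unit_key <- switch(granularity,
    cluster = paste(out$sample_id, out$cluster_id, sep = "\r"),
    segment = paste(out$sample_id, out$segment_id, sep = "\r"),
    sample = out$sample_id
  )
  V <- nrow(H)
  post <- matrix(NA_real_, nrow(out), V,
                 dimnames = list(NULL, rownames(H)))
  best <- integer(nrow(out))
  unassigned <- logical(nrow(out))
  expo <- list()
  for (u in unique(unit_key)) {
    rows <- which(unit_key == u)
    d <- estimate_exposures(count_vector96(out$channel[rows]), H,
                            method = method, min_exposure = min_exposure)
    pa <- posterior_assign(out$channel[rows], d, H)
    post[rows, ] <- pa$posterior
    best[rows] <- pa$best
    unassigned[rows] <- pa$unassigned
    expo[[u]] <- tibble::tibble(
      sample_id = out$sample_id[rows[1]],
      unit_id = switch(granularity,
        cluster = out$cluster_id[rows[1]],
        segment = out$segment_id[rows[1]],
        sample = NA_integer_),
      granularity = granularity,
      signature = rownames(H), exposure = as.numeric(d)
    )
  }
  colnames(post) <- paste0("p_", rownames(H))
  out <- dplyr::bind_cols(out, tibble::as_tibble(post))
  out$best_signature <- ifelse(unassigned, NA_character_, rownames(H)[best])
  out$max_posterior <- ifelse(unassigned, NA_real_,
                              post[cbind(seq_len(nrow(post)), best)])
  out$unassigned <- unassigned
  attr(out, "exposures") <- dplyr::bind_rows(expo)
  attr(out, "signature_ids") <- rownames(H)
  attr(out, "granularity") <- granularity
  class(out) <- c("mut_assignment", class(out))
  out
}

#' Fraction of correctly assigned mutations
#'
#' @param assignment A `mut_assignment` (or its `best_signature` vector).
#' @param truth Character vector of true per-mutation signature ids, same
#'   length as the catalog.
#' @return Fraction of non-flagged mutations whose argmax signature equals
#'   the truth.
#' @export
assignment_accuracy <- function(assignment, truth) {
  best <- if (is.data.frame(assignment)) assignment$best_signature else assignment
  if (length(best) != length(truth)) abort("assignment/truth length mismatch")
  ok <- !is.na(best)
  if (!any(ok)) return(NA_real_)
  mean(best[ok] == truth[ok])
}

#' @export
print.mut_assignment <- function(x, ...) {
  cat(sprintf("# Signature assignment: %d mutation(s), %d unassigned (%s-level exposures)\n",
              nrow(x), sum(x$unassigned), attr(x, "granularity") %||% "?"))
  NextMethod()
  invisible(x)
}
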