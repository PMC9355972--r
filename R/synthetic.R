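#' A small well-separated signature matrix for simulation and tests
#'
#' Synthetic signatures with concentrated, partially overlapping supports,
#' shaped like the most distinctive real processes (a few dominant peaks
#' plus a shared CpG-transition component): each signature puts 85% of its
#' mass uniformly on six private channels of its own substitution class and
#' the remaining 15% on the four C>T-at-NpCpG channels that all signatures
#' share, and is exactly zero elsewhere.  The shared block makes posterior
#' assignment genuinely probabilistic (there the posterior equals the
#' regional exposures), while the small supports keep the effective
#' dimension of any few-signature mixture well below the BIC penalty, the
#' regime in which the merge criterion is consistent.  This is a synthetic
#' stand-in used so the test suite needs no external signature download;
#' any COSMIC-layout matrix read with [read_signature_matrix()] can be used
#' instead.
#'
#' @param V Number of signatures, at most 6 (default 4).
#' @return A V x 96 signature matrix with rownames `SYN1..SYNV`.
#' @export
toy_signature_matrix <- function(V = 4L) {
  stopifnot(V >= 1, V <= 6)
  # own substitution class per signature: C>A, T>C, T>A, C>G, T>G, C>T
  classes <- c(1L, 5L, 4L, 2L, 6L, 3L)[seq_len(V)]
  shared <- 2L * 16L + c(2L, 6L, 10L, 14L) + 1L  # N[C>T]G channels
  H <- matrix(0, nrow = V, ncol = 96L)
  for (v in seq_len(V)) {
    own <- (classes[v] - 1L) * 16L + c(0L, 1L, 4L, 5L, 8L, 9L) + 1L
    own <- setdiff(own, shared)
    H[v, own] <- 0.85 / length(own)
    H[v, shared] <- 0.15 / 4
  }
  rownames(H) <- paste0("SYN", seq_len(V))
  colnames(H) <- sbs96_channels()
  H
}

#' Specify one simulated genomic region
#'
#' @param chrom Chromosome name (default `"chr1"`).
#' @param n Number of mutations in the region (>= 1).
#' @param exposures Numeric vector of signature proportions (length V,
#'   nonnegative, summing to 1).
#' @param signal_level Latent signal level 1, 2 or 3 (low/middle/high).
#' @param ccf_mode `"clonal"` (CCF ~ Beta(50, 2), mode near 1) or
#'   `"subclonal"` (CCF ~ Beta(5, 15)).
#' @param mean_spacing Mean inter-mutation spacing in bp (geometric;
#'   default 5000).
#' @return One-row tibble usable in the region list of
#'   [simulate_catalog()].
#' @export
region_spec <- function(chrom = "chr1", n, exposures, signal_level = 2L,
                        ccf_mode = c("clonal", "subclonal"),
                        mean_spacing = 5000) {
  ccf_mode <- match.arg(ccf_mode)
  if (n < 1) abort("region mutation_count must be >= 1")
  exposures <- as.numeric(exposures)
  if (any(exposures < 0) || abs(sum(exposures) - 1) > 1e-8) {
    abort("region exposures must be nonnegative and sum to 1")
  }
  stopifnot(signal_level %in% 1:3)
  tibble::tibble(
    chrom = chrom, n = as.integer(n), exposures = list(exposures),
    signal_level = as.integer(signal_level), ccf_mode = ccf_mode,
    mean_spacing = mean_spacing
  )
}

#' Simulate a mutation catalog from region-wise signature mixtures
#'
#' Generates a coordinate-sorted catalog in which each region's mutations
#' draw a signature from the region's exposure vector and a channel from
#' that signature's 96-channel profile (the multinomial model the
#' segmentation assumes), with positions laid down by cumulative geometric
#' spacing.  Regions on the same chromosome are placed consecutively,
#' separated by a spacer of 20x the mean spacing.  Identical seeds give
#' byte-identical output.
#'
#' @param regions List of [region_spec()] rows (or a tibble of them).
#' @param H Signature matrix whose row count matches the exposure vectors.
#' @param seed Integer seed.
#' @param sample_id Sample name (default `"synthetic"`).
#' @return List with `catalog` (a `mut_catalog` with `ref`/`alt`/`context`
#'   decoded from the channel) and `truth` (tibble aligned with the catalog
#'   rows: `true_signature`, `region_id`, `cluster_id` — regions sharing an
#'   exposure vector share a cluster id — `signal_level`, `ccf_mode`).
#' @export
simulate_catalog <- function(regions, H, seed, sample_id = "synthetic") {
  if (is.data.frame(regions)) {
    regions <- split(regions, seq_len(nrow(regions)))
  } else if (!is.data.frame(regions[[1]])) {
    abort("`regions` must be region_spec() rows")
  }
  regions <- dplyr::bind_rows(regions)
  H <- validate_signature_matrix(H)
  V <- nrow(H)
  bad <- vapply(regions$exposures, length, integer(1)) != V
  if (any(bad)) abort("exposure vector length does not match signature matrix")
  if (any(regions$n < 1)) abort("region mutation_count must be >= 1")

  # regions sharing an exposure vector form one true cluster
  expo_key <- vapply(regions$exposures, paste, character(1), collapse = ",")
  regions$cluster_id <- match(expo_key, unique(expo_key)) - 1L

  withr::with_seed(seed, {
    pieces <- vector("list", nrow(regions))
    next_pos <- list()
    for (r in seq_len(nrow(regions))) {
      rg <- regions[r, ]
      n <- rg$n
      start <- next_pos[[rg$chrom]] %||% 0L
      gaps <- rgeom(n, 1 / rg$mean_spacing) + 1L
      pos <- start + cumsum(as.numeric(gaps))
      next_pos[[rg$chrom]] <- pos[n] + 20L * rg$mean_spacing
      sig <- sample.int(V, n, replace = TRUE, prob = rg$exposures[[1]])
      channel <- integer(n)
      for (v in unique(sig)) {
        sel <- sig == v
        channel[sel] <- sample.int(96L, sum(sel), replace = TRUE,
                                   prob = H[v, ]) - 1L
      }
      pieces[[r]] <- tibble::tibble(
        chrom = rg$chrom, pos = as.integer(pos), channel = channel,
        true_signature = rownames(H)[sig], region_id = r - 1L,
        cluster_id = rg$cluster_id, signal_level = rg$signal_level,
        ccf_mode = rg$ccf_mode
      )
    }
    all <- dplyr::bind_rows(pieces)
    all <- dplyr::arrange(all, .data$chrom, .data$pos)
    dec <- decode_channel(all$channel)
    catalog <- as_mut_catalog(tibble::tibble(
      sample_id = sample_id, chrom = all$chrom, pos = all$pos,
      ref = dec$ref, alt = dec$alt, context = dec$context,
      channel = all$channel
    ))
    truth <- all[, c("chrom", "pos", "true_signature", "region_id",
                     "cluster_id", "signal_level", "ccf_mode")]
    list(catalog = catalog, truth = truth)
  })
}

#' Inject kataegis-like runs into a simulated catalog
#'
#' Adds `events` runs of `size` tightly spaced mutations (inter-mutation
#' spacing `spacing_bp`, which must be below 1000 so injected runs satisfy
#' the detection rule) at loci at least 10 kb away from existing mutations
#' and from each other, with channels drawn from one signature's profile.
#'
#' @param catalog A simulated catalog.
#' @param events Number of runs to inject.
#' @param size Mutations per run.
#' @param spacing_bp Spacing within runs (< 1000).
#' @param signature Row name or index in `H`.
#' @param H Signature matrix.
#' @param seed Integer seed.
#' @return The augmented, re-sorted catalog; attribute `injected` is a
#'   tibble of the injected loci (`chrom`, `start`, `end`, `size`).
#' @export
simulate_kataegis <- function(catalog, events, size, spacing_bp, signature,
                              H, seed) {
  if (spacing_bp >= 1000) {
    abort("spacing_bp must be < 1000 so injected runs meet the detection rule")
  }
  catalog <- assert_catalog(catalog)
  H <- validate_signature_matrix(H)
  v <- if (is.character(signature)) match(signature, rownames(H)) else signature
  if (is.na(v)) abort("unknown signature")
  run_span <- (size - 1L) * spacing_bp
  withr::with_seed(seed, {
    injected <- list()
    new_rows <- list()
    for (e in seq_len(events)) {
      chrom <- sample(unique(catalog$chrom), 1L)
      occ_pos <- c(catalog$pos[catalog$chrom == chrom],
                   unlist(lapply(injected, function(i) {
                     if (i$chrom == chrom) c(i$start, i$end) else NULL
                   })))
      hi <- max(occ_pos) + 1e6
      start <- NA_integer_
      for (try in seq_len(1000L)) {
        cand <- as.integer(runif(1, 1, hi))
        if (all(abs(occ_pos - cand) >= 10000L + run_span)) { start <- cand; break }
      }
      if (is.na(start)) abort("no room on the simulated chromosome for injection")
      pos <- start + spacing_bp * (seq_len(size) - 1L)
      channel <- sample.int(96L, size, replace = TRUE, prob = H[v, ]) - 1L
      dec <- decode_channel(channel)
      new_rows[[e]] <- tibble::tibble(
        sample_id = catalog$sample_id[1], chrom = chrom, pos = pos,
        ref = dec$ref, alt = dec$alt, context = dec$context,
        channel = channel
      )
      injected[[e]] <- tibble::tibble(chrom = chrom, start = pos[1],
                                      end = pos[size], size = size)
    }
    out <- as_mut_catalog(dplyr::bind_rows(
      tibble::as_tibble(catalog)[, c("sample_id", "chrom", "pos", "ref",
                                     "alt", "context", "channel")],
      dplyr::bind_rows(new_rows)
    ))
    attr(out, "injected") <- dplyr::bind_rows(injected)
    out
  })
}

#' Attach simulated CCF and signal values
#'
#' Gives every mutation a cancer cell fraction drawn from its region's
#' clonality mode — clonal Beta(50, 2) (mode near 1) or subclonal
#' Beta(5, 15) — and a continuous signal drawn uniformly within its
#' region's level band (level l covers ((l-1)/3, l/3), centered draws of
#' half-width 0.1 keep values inside the band), emulating a smooth
#' genome-wide track with three-level structure.  Deterministic per seed.
#'
#' @param catalog A simulated catalog.
#' @param truth The matching truth table from [simulate_catalog()].
#' @param seed Integer seed.
#' @return The catalog with `ccf` and `signal` columns.
#' @export
attach_ccf_and_signal <- function(catalog, truth, seed) {
  catalog <- assert_catalog(catalog)
  if (nrow(truth) != nrow(catalog)) abort("truth does not cover the catalog")
  withr::with_seed(seed, {
    n <- nrow(catalog)
    clonal <- truth$ccf_mode == "clonal"
    ccf <- numeric(n)
    ccf[clonal] <- rbeta(sum(clonal), 50, 2)
    ccf[!clonal] <- rbeta(sum(!clonal), 5, 15)
    centers <- (truth$signal_level - 0.5) / 3
    signal <- centers + runif(n, -0.1, 0.1)
    catalog$ccf <- ccf
    catalog$signal <- signal
    catalog
  })
}

#' Bayes-optimal assignment accuracy of a region mixture
#'
#' The accuracy an oracle achieves when it knows each region's true
#' exposures `d_r` and assigns every channel `c` to
#' `argmax_v d_rv * h_vc`: `sum_r w_r * sum_c max_v d_rv * h_vc`, with
#' `w_r` the region's share of mutations.  Estimated accuracies on
#' simulated genomes converge to this rate from below.
#'
#' @param regions Region list/tibble as for [simulate_catalog()].
#' @param H Signature matrix.
#' @return Scalar rate in \[0, 1\].
#' @export
bayes_accuracy <- function(regions, H) {
  if (!is.data.frame(regions)) regions <- dplyr::bind_rows(regions)
  H <- validate_signature_matrix(H)
  w <- regions$n / sum(regions$n)
  per_region <- vapply(regions$exposures, function(d) {
    sum(apply(d * H, 2, max))
  }, numeric(1))
  sum(w * per_region)
}
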