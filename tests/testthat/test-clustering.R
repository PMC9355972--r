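segments_from_channel_sets <- function(channel_sets, chrom = NULL) {
  # build a catalog whose local merge keeps each channel set as one segment
  if (is.null(chrom)) chrom <- paste0("chr", seq_along(channel_sets))
  pieces <- purrr::map2(channel_sets, chrom, function(ch, cr) {
    dec <- decode_channel(as.integer(ch))
    tibble::tibble(sample_id = "s1", chrom = cr,
                   pos = 1000L * seq_along(ch),
                   ref = dec$ref, alt = dec$alt, channel = as.integer(ch))
  })
  cat <- as_mut_catalog(dplyr::bind_rows(pieces))
  segment_catalog(cat)
}

test_that("identical distant segments merge into one cluster, disjoint ones stay apart", {
  seg_same <- segments_from_channel_sets(list(rep(0L, 30), rep(0L, 30)))
  cl_same <- cluster_segments(seg_same)
  expect_equal(nrow(attr(cl_same, "clusters")), 1L)
  expect_equal(unique(cl_same$cluster_id), 0L)

  seg_diff <- segments_from_channel_sets(list(rep(0L, 30), rep(1L, 30)))
  cl_diff <- cluster_segments(seg_diff)
  expect_equal(nrow(attr(cl_diff, "clusters")), 2L)
})

test_that("cluster profiles are pooled MLEs", {
  seg <- segments_from_channel_sets(list(rep(0L, 30), rep(0L, 30)))
  cl <- cluster_segments(seg)
  pr <- cluster_profiles(cl)
  expect_equal(pr$profile[[1]][1], 1)
  expect_equal(sum(pr$profile[[1]]), 1)

  seg2 <- segments_from_channel_sets(list(rep(0L, 30), rep(1L, 30)))
  cl2 <- cluster_segments(seg2)
  # force-merge check through pooled counts: equal-n pure segments -> 0.5/0.5
  pooled <- mle_profile(seg2$counts[[1]] + seg2$counts[[2]])
  expect_equal(pooled[1:2], c(0.5, 0.5))
  # singleton cluster profile equals the segment's own MLE
  expect_equal(pr <- cluster_profiles(cl2)$profile[[1]],
               mle_profile(seg2$counts[[1]]))
})

test_that("greedy clustering matches brute-force BIC over all set partitions of 5 segments", {
  cfg <- seg_config()
  set.seed(23)
  # five segments from two latent mixtures (3 vs 2)
  mix_a <- c(0L, 1L, 2L)
  mix_b <- c(40L, 41L)
  sets <- list(sample(mix_a, 40, TRUE), sample(mix_b, 40, TRUE),
               sample(mix_a, 40, TRUE), sample(mix_a, 40, TRUE),
               sample(mix_b, 40, TRUE))
  counts <- lapply(sets, count_vector96)

  # brute-force optimum over all 52 set partitions
  parts <- set_partitions(5)
  bics <- vapply(parts, function(p) {
    clustering_bic(lapply(p, function(idx) Reduce(`+`, counts[idx])), cfg)
  }, numeric(1))
  best <- parts[[which.min(bics)]]
  canon <- function(p) unname(lapply(p[order(vapply(p, min, numeric(1)))], sort))
  expect_equal(canon(best), list(c(1L, 3L, 4L), c(2L, 5L)))

  # the greedy result recovers the same partition
  seg <- segments_from_channel_sets(sets)
  cl <- cluster_segments(seg, cfg)
  memb <- split(seq_len(5), cl$cluster_id)
  expect_equal(canon(memb), canon(best))

  # greedy path deltas equal brute-force clustering_bic differences
  pooled <- counts
  repeat {
    K <- length(pooled)
    if (K == 1) break
    deltas <- matrix(NA_real_, K, K)
    for (a in seq_len(K - 1)) for (b in (a + 1):K) {
      merged <- c(pooled[-c(a, b)], list(pooled[[a]] + pooled[[b]]))
      deltas[a, b] <- clustering_bic(merged, cfg) - clustering_bic(pooled, cfg)
    }
    bestd <- min(deltas, na.rm = TRUE)
    if (bestd > 0) break
    hit <- which(deltas == bestd, arr.ind = TRUE)[1, ]
    pooled[[hit[1]]] <- pooled[[hit[1]]] + pooled[[hit[2]]]
    pooled[[hit[2]]] <- NULL
  }
  expect_equal(length(pooled), nrow(attr(cl, "clusters")))
  expect_equal(sort(vapply(pooled, sum, numeric(1))),
               sort(attr(cl, "clusters")$N_k * 1.0))
})

test_that("clustering is invariant to segment input order and BIC-consistent", {
  sim <- simulate_catalog(list(
    region_spec(chrom = "chr1", n = 400, exposures = c(0.8, 0.2, 0, 0)),
    region_spec(chrom = "chr2", n = 400, exposures = c(0, 0.2, 0.8, 0)),
    region_spec(chrom = "chr3", n = 400, exposures = c(0.8, 0.2, 0, 0))
  ), toy_signature_matrix(), seed = 9)
  seg <- segment_catalog(sim$catalog)
  cl <- cluster_segments(seg)
  expect_lte(nrow(attr(cl, "clusters")), nrow(seg))
  # BIC recomputed from scratch matches, and is <= the all-singletons BIC
  g <- glance(cl)
  expect_equal(g$bic, clustering_bic(attr(cl, "clusters")$counts,
                                     attr(cl, "config")), tolerance = 1e-9)
  expect_lte(g$bic, clustering_bic(seg$counts, attr(seg, "config")) + 1e-9)

  # shuffle segment rows: same final partition of the mutations
  perm <- sample(nrow(seg))
  seg_shuf <- seg[perm, ]
  attr(seg_shuf, "config") <- attr(seg, "config")
  class(seg_shuf) <- class(seg)
  cl_shuf <- cluster_segments(seg_shuf)
  ref_part <- split(paste(seg$chrom, seg$start_idx), cl$cluster_id)
  shuf_part <- split(paste(seg_shuf$chrom, seg_shuf$start_idx), cl_shuf$cluster_id)
  canon <- function(p) sort(unname(vapply(p, function(x) paste(sort(x), collapse = "|"),
                                          character(1))))
  expect_equal(canon(shuf_part), canon(ref_part))
})
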