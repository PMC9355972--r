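test_that("kataegis detection applies the >=6 / <1000 bp rule strictly", {
  ev <- detect_kataegis(spaced_catalog(rep(500L, 6)))   # 7 mutations at 500 bp
  expect_equal(nrow(ev), 1L)
  expect_equal(ev$size, 7L)

  # spacing exactly 1000 bp never qualifies (strict <)
  expect_equal(nrow(detect_kataegis(spaced_catalog(rep(1000L, 5)))), 0L)
  # 5 mutations at 10 bp: run too short
  expect_equal(nrow(detect_kataegis(spaced_catalog(rep(10L, 4)))), 0L)
  # maximality: a long close run flanked by distant mutations is one event
  ev2 <- detect_kataegis(spaced_catalog(c(50000L, rep(100L, 7), 50000L)))
  expect_equal(nrow(ev2), 1L)
  expect_equal(ev2$size, 8L)
})

test_that("kataegis events double when the catalog is duplicated at an offset", {
  base <- spaced_catalog(c(rep(100L, 7), 5000L, rep(200L, 9)))
  ev1 <- detect_kataegis(base)
  shifted <- dplyr::mutate(tibble::as_tibble(base),
                           pos = pos + max(base$pos) + 10000L)
  both <- as_mut_catalog(dplyr::bind_rows(tibble::as_tibble(base), shifted))
  ev2 <- detect_kataegis(both)
  expect_equal(nrow(ev2), 2L * nrow(ev1))
  expect_equal(sum(ev2$size), 2L * sum(ev1$size))
})

test_that("hypermutated samples are excluded from kataegis analysis", {
  cat <- spaced_catalog(rep(100L, 20))
  ev <- detect_kataegis(cat, max_mutations = 10L)
  expect_equal(nrow(ev), 0L)
  expect_equal(attr(ev, "skipped_samples"), "s1")
})

test_that("Fisher enrichment p-values match hypergeometric tail sums", {
  # the fully concentrated 6-vs-6 table
  tab <- matrix(c(6, 0, 0, 6), 2)
  p <- fisher.test(tab, alternative = "greater")$p.value
  expect_equal(p, 1 / 924, tolerance = 1e-12)
  expect_equal(p, fisher_greater_brute(6, 0, 0, 6), tolerance = 1e-12)

  set.seed(12)
  for (i in 1:10) {
    a <- sample(0:8, 1); b <- sample(0:8, 1)
    c_ <- sample(0:50, 1); d <- sample(10:80, 1)
    if ((a + b) == 0 || (a + c_) == 0) next
    p_pkg <- fisher.test(matrix(c(a, b, c_, d), 2),
                         alternative = "greater")$p.value
    expect_equal(p_pkg, fisher_greater_brute(a, b, c_, d), tolerance = 1e-9)
  }
})

test_that("per-signature enrichment calls concentrated events and not background-like ones", {
  # 10000-mutation sample, 1% signature B; one event of 10 pure B mutations
  n <- 10000L
  best <- rep("A", n)
  best[5001:5100] <- "B"           # sample background: 1% B
  best[101:110] <- "B"             # the kataegic event, all B
  assignment <- tibble::tibble(sample_id = "s1", best_signature = best)
  events <- tibble::tibble(sample_id = "s1", chrom = "chr1",
                           start = 1L, end = 10L, size = 10L,
                           start_row = 101L, end_row = 110L)
  enr <- kataegis_enrichment(events, assignment)
  pB <- enr$p_value[enr$signature == "B"]
  expect_lt(pB, 1e-10)
  expect_true(enr$enriched[enr$signature == "B"])

  # event with the sample-wide composition: no association
  best2 <- rep(c("A", "B"), n / 2)
  assignment2 <- tibble::tibble(sample_id = "s1", best_signature = best2)
  events2 <- tibble::tibble(sample_id = "s1", chrom = "chr1",
                            start = 1L, end = 10L, size = 10L,
                            start_row = 101L, end_row = 110L)
  enr2 <- kataegis_enrichment(events2, assignment2)
  expect_true(all(enr2$p_value > 0.2))

  expect_error(kataegis_enrichment(
    dplyr::mutate(events, sample_id = "missing"), assignment), "absent")
})

test_that("CCF discordance: identical distributions are null, disjoint ones maximal", {
  mk <- function(ccf_a, ccf_b) {
    tibble::tibble(
      sample_id = "s1",
      best_signature = rep(c("A", "B"), c(length(ccf_a), length(ccf_b))),
      ccf = c(ccf_a, ccf_b)
    )
  }
  same <- seq(0.1, 0.9, length.out = 50)
  r1 <- ccf_pair_discordance(mk(same, same))
  expect_equal(r1$statistic, 0)
  expect_equal(r1$p_value, 1)
  expect_false(r1$discordant)

  r2 <- ccf_pair_discordance(mk(rep(1.0, 50), rep(0.1, 50)))
  expect_equal(r2$statistic, 1)
  expect_lt(r2$fdr_q, 1e-10)
  expect_true(r2$discordant)
  expect_equal(r2$earlier, "A")  # higher median CCF = earlier

  # below min_per_signature: empty result with a message
  expect_message(r3 <- ccf_pair_discordance(mk(rep(1, 5), rep(0, 5))),
                 "min_per_signature")
  expect_equal(nrow(r3), 0L)
})

test_that("BH correction matches a brute-force step-up and controls null discoveries", {
  set.seed(88)
  rows <- lapply(1:200, function(i) {
    tibble::tibble(sample_id = paste0("s", i),
                   best_signature = rep(c("A", "B"), each = 30),
                   ccf = rbeta(60, 2, 2))
  })
  res <- ccf_pair_discordance(dplyr::bind_rows(rows))
  expect_equal(nrow(res), 200L)
  # pre-FDR false positives near alpha; post-FDR essentially none
  expect_lt(mean(res$p_value < 0.05), 0.12)
  expect_lte(sum(res$discordant), 2L)
  expect_equal(res$fdr_q, bh_adjust_brute(res$p_value), tolerance = 1e-12)
  expect_equal(res$fdr_q, p.adjust(res$p_value, "BH"), tolerance = 1e-12)
  # monotone non-decreasing in p-rank
  o <- order(res$p_value)
  expect_true(all(diff(res$fdr_q[o]) >= -1e-12))
})
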