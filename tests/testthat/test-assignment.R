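toy2 <- function() {
  # two signatures living on two channels only: h1 = (0.9, 0.1), h2 = (0.2, 0.8)
  H <- matrix(0, 2, 96)
  H[1, 1:2] <- c(0.9, 0.1)
  H[2, 1:2] <- c(0.2, 0.8)
  rownames(H) <- c("A", "B")
  H
}

test_that("exposure refitting recovers exact mixtures", {
  H <- toy_signature_matrix()
  # counts exactly proportional to one signature -> unit exposure vector
  counts <- 2400 * H[2, ]
  d <- estimate_exposures(counts, H)
  expect_equal(as.numeric(d), c(0, 1, 0, 0), tolerance = 1e-6)

  # exactly solvable 2x2 system: 0.5*h1 + 0.5*h2 = (0.55, 0.45)
  d2 <- estimate_exposures(count_vector96(rep(c(0L, 1L), c(55L, 45L))), toy2())
  expect_equal(as.numeric(d2), c(0.5, 0.5), tolerance = 1e-6)
  d2n <- estimate_exposures(count_vector96(rep(c(0L, 1L), c(55L, 45L))), toy2(),
                            method = "nnls")
  expect_equal(as.numeric(d2n), c(0.5, 0.5), tolerance = 1e-6)
})

test_that("EM recovers seeded mixtures, is monotone, and agrees with NNLS", {
  H <- toy_signature_matrix()
  d_true <- c(0.5, 0.3, 0.2, 0)
  set.seed(31)
  sig <- sample.int(4, 10000, replace = TRUE, prob = d_true)
  ch <- vapply(sig, function(v) sample.int(96, 1, prob = H[v, ]) - 1L,
               integer(1))
  counts <- count_vector96(ch)
  d_em <- estimate_exposures(counts, H)
  expect_lt(sum(abs(d_em - d_true)) / 2, 0.05)  # total variation vs truth

  ll <- attr(d_em, "loglik_trace")
  expect_true(all(diff(ll) >= -1e-9))  # EM monotonicity

  d_nnls <- estimate_exposures(counts, H, method = "nnls")
  expect_lt(sum(abs(d_em - d_nnls)) / 2, 0.02)
})

test_that("exposure edge cases: empty counts, unexplained channels, thresholding", {
  H <- toy2()
  expect_error(estimate_exposures(integer(96), H), "empty")
  counts <- count_vector96(c(0L, 0L, 1L, 50L))  # channel 50 outside support
  expect_warning(d <- estimate_exposures(counts, H), "excluded")
  expect_equal(sum(d), 1)
  d_thr <- suppressWarnings(
    estimate_exposures(counts, H, min_exposure = 0.5))
  expect_equal(sum(d_thr), 1)
  expect_equal(sum(d_thr > 0), 1L)
})

test_that("posterior assignment follows h_vc * d_v normalization", {
  H <- toy2()
  pa <- posterior_assign(0L, d = c(0.5, 0.5), H)
  expect_equal(as.numeric(pa$posterior), c(0.45, 0.10) / 0.55, tolerance = 1e-12)
  expect_equal(pa$best, 1L)

  # degenerate exposures pass through
  pa1 <- posterior_assign(c(0L, 1L), d = c(1, 0), H)
  expect_equal(pa1$posterior[, 1], c(1, 1))
  expect_equal(pa1$best, c(1L, 1L))

  # equal likelihood across signatures -> posterior equals d
  Heq <- matrix(0, 2, 96); Heq[, 1] <- 0.5; Heq[, 2] <- 0.5
  rownames(Heq) <- c("A", "B")
  pa2 <- posterior_assign(0L, d = c(0.3, 0.7), Heq)
  expect_equal(as.numeric(pa2$posterior), c(0.3, 0.7))

  # zero-likelihood channel -> flagged unassigned, not fabricated
  pa3 <- posterior_assign(50L, d = c(0.5, 0.5), H)
  expect_true(pa3$unassigned)
  expect_true(is.na(pa3$best))

  # rows sum to 1 for all assignable channels under random exposures
  set.seed(4)
  d <- rgamma(4, 1); d <- d / sum(d)
  pa4 <- posterior_assign(0:95, d, toy_signature_matrix())
  sums <- rowSums(pa4$posterior)
  expect_equal(as.numeric(sums[!pa4$unassigned]),
               rep(1, sum(!pa4$unassigned)), tolerance = 1e-9)
})

test_that("supplying true exposures reproduces the Bayes-optimal channel rule", {
  H <- toy_signature_matrix()
  d <- c(0.6, 0.3, 0.1, 0)
  pa <- posterior_assign(0:95, d, H)
  for (c_ in which(!pa$unassigned)) {
    expect_equal(pa$best[c_], unname(which.max(d * H[, c_])))
  }
})

test_that("end-to-end assignment reaches near-Bayes accuracy and accuracy is counted correctly", {
  H <- toy_signature_matrix()
  regions <- list(
    region_spec(chrom = "chr1", n = 2000, exposures = c(0.6, 0.3, 0.1, 0)),
    region_spec(chrom = "chr2", n = 2000, exposures = c(0.1, 0.2, 0.7, 0)))
  sim <- simulate_catalog(regions, H, seed = 77)
  seg <- segment_catalog(sim$catalog)
  cl <- cluster_segments(seg)
  a <- assign_signatures(sim$catalog, cl, H)
  acc <- assignment_accuracy(a, sim$truth$true_signature)
  expect_gt(acc, bayes_accuracy(regions, H) - 0.03)
  expect_lte(acc, 1)

  expect_equal(assignment_accuracy(a, a$best_signature), 1)
  flipped <- ifelse(a$best_signature == "SYN1", "SYN2", "SYN1")
  expect_equal(assignment_accuracy(a$best_signature, flipped), 0)
  expect_error(assignment_accuracy(a, sim$truth$true_signature[-1]), "mismatch")
})

test_that("cluster-level exposures beat sample-level ones on regionally heterogeneous genomes", {
  H <- toy_signature_matrix()
  regions <- list(
    region_spec(chrom = "chr1", n = 1500, exposures = c(0.85, 0.15, 0, 0)),
    region_spec(chrom = "chr2", n = 1500, exposures = c(0, 0.15, 0.85, 0)))
  sim <- simulate_catalog(regions, H, seed = 55)
  seg <- segment_catalog(sim$catalog)
  cl <- cluster_segments(seg)
  acc <- vapply(c("cluster", "segment", "sample"), function(g) {
    a <- assign_signatures(sim$catalog, cl, H, granularity = g)
    assignment_accuracy(a, sim$truth$true_signature)
  }, numeric(1))
  expect_gt(acc[["cluster"]], acc[["sample"]])
  expect_gte(acc[["cluster"]], acc[["segment"]] - 1e-9)
})
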