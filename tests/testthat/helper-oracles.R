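# Independent oracles and tiny fixture builders shared across test files.

# count vector with `n` mutations on the given 0-based channel(s)
pure_counts <- function(channel, n) {
  ch <- rep(channel, length.out = n)
  count_vector96(as.integer(ch))
}

# all contiguous partitions of 1..T (compositions), as lists of index vectors
contiguous_partitions <- function(T) {
  if (T == 1) return(list(list(1L)))
  out <- list()
  for (mask in 0:(2^(T - 1) - 1)) {
    cuts <- which(bitwAnd(mask, 2^(0:(T - 2))) > 0)
    bounds <- c(0L, cuts, T)
    out[[length(out) + 1L]] <-
      lapply(seq_len(length(bounds) - 1L), function(i) {
        (bounds[i] + 1L):bounds[i + 1L]
      })
  }
  out
}

# all set partitions of 1..n (Bell numbers; n <= 6 in tests)
set_partitions <- function(n) {
  if (n == 1) return(list(list(1L)))
  smaller <- set_partitions(n - 1)
  out <- list()
  for (p in smaller) {
    for (b in seq_along(p)) {
      q <- p
      q[[b]] <- c(q[[b]], n)
      out[[length(out) + 1L]] <- q
    }
    out[[length(out) + 1L]] <- c(p, list(n))
  }
  out
}

# brute-force Benjamini-Hochberg: reject largest k with p_(k) <= k/m * alpha,
# and step-up adjusted values
bh_adjust_brute <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- numeric(m)
  prev <- 1
  for (k in m:1) {
    prev <- min(prev, p[o[k]] * m / k)
    adj[o[k]] <- prev
  }
  adj
}

# one-sided (enrichment) Fisher p by direct hypergeometric tail summation
fisher_greater_brute <- function(a, b, c_, d) {
  m <- a + c_        # total successes
  n <- b + d         # total failures
  k <- a + b         # draws (event size)
  sum(vapply(a:min(m, k), function(x) {
    choose(m, x) * choose(n, k - x) / choose(m + n, k)
  }, numeric(1)))
}

# evenly spaced single-channel catalog (kataegis fixtures)
spaced_catalog <- function(spacings, chrom = "chr1", sample_id = "s1",
                           channel = 0L) {
  pos <- cumsum(c(10000L, spacings))
  dec <- decode_channel(rep(channel, length(pos)))
  as_mut_catalog(tibble::tibble(
    sample_id = sample_id, chrom = chrom, pos = pos,
    ref = dec$ref, alt = dec$alt, channel = rep(channel, length(pos))
  ))
}

# a two-regime single-chromosome simulation used by several tests
two_regime_sim <- function(n_per, seed, H = toy_signature_matrix(),
                           d_a = c(0.8, 0.15, 0.05, 0),
                           d_b = c(0.05, 0.15, 0.8, 0)) {
  simulate_catalog(
    list(region_spec(chrom = "chr1", n = n_per, exposures = d_a),
         region_spec(chrom = "chr1", n = n_per, exposures = d_b)),
    H, seed = seed
  )
}
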