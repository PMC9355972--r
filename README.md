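# sigsegment

Mutational-signature analysis at the resolution of **individual somatic
mutations**.  Conventional signature refitting summarizes a whole cancer
genome by one exposure vector, but mutational processes act regionally:
the signature mixture around a given mutation can differ sharply from the
genome-wide average.  `sigsegment` segments each chromosome's
coordinate-sorted SNVs into runs with homogeneous trinucleotide spectra,
clusters non-adjacent segments that share a spectrum, refits signature
exposures per cluster, and assigns every mutation to the signature
maximizing its posterior probability.  It is aimed at cancer-genomics
analysts working from VCF/MAF/TSV somatic calls and a COSMIC-style
signature catalog.

## The model in brief

Each mutation is a draw from `Mult(1; p)` over the 96 pyrimidine-collapsed
trinucleotide channels, with a shared channel distribution `q_t` inside a
segment.  A segmentation `S = {S_1..S_T}` of a chromosome's `N` mutations
is scored by a modified BIC

    BIC(S) = -2 Σ_t Σ_j Σ_i I(m_tj = MT_i) ln q̂_ti + λ1 T ln N ,   λ1 = 5

and neighboring segments are merged greedily while the merge lowers (or
leaves unchanged) the BIC.  Segments are then clustered genome-wide under
the analogous objective with penalty `λ2 K ln N` (`λ2 = 5`), merged pairs
need not be adjacent.  For a mutation with channel `c` in cluster `r` with
refit exposures `d_r` (EM on the multinomial likelihood; NNLS available as
a cross-check), the posterior over signatures `h_v` is

    P(v | c, r) = h_vc d_rv / Σ_w h_wc d_rw ,

and the arg-max signature is the mutation's call.  Downstream statistics:
an exact permutation test on three-level Shannon entropy for the
concordance of clusters in replication timing or cancer cell fraction
(CCF); kataegis detection (≥ 6 consecutive mutations, inter-mutation
distance < 1000 bp) with one-sided Fisher enrichment per signature; and
pairwise two-sample Kolmogorov–Smirnov comparison of per-signature CCF
distributions with Benjamini–Hochberg control.

## Worked example

```r
library(sigsegment)

H <- toy_signature_matrix()                       # 4 bundled synthetic signatures
sim <- simulate_catalog(list(
  region_spec(chrom = "chr1", n = 2000, exposures = c(0.6, 0.3, 0.1, 0)),
  region_spec(chrom = "chr2", n = 2000, exposures = c(0.1, 0.2, 0.7, 0))),
  H, seed = 1)

seg <- segment_catalog(sim$catalog)               # per-chromosome BIC segmentation
cl  <- cluster_segments(seg)                      # genome-wide BIC clustering
a   <- assign_signatures(sim$catalog, cl, H)      # per-mutation posteriors

glance(cl)
#> # A tibble: 1 × 4
#>   sample_id     K     N    bic
#> 1 synthetic     2  4000 23086.

exposures(a)
#> # A tibble: 8 × 5
#>   sample_id unit_id granularity signature exposure
#> 1 synthetic       0 cluster     SYN1      5.95e- 1
#> 2 synthetic       0 cluster     SYN2      3.00e- 1
#> 3 synthetic       0 cluster     SYN3      1.05e- 1
#> 4 synthetic       0 cluster     SYN4      2.59e-10
#> 5 synthetic       1 cluster     SYN1      9.79e- 2
#> 6 synthetic       1 cluster     SYN2      2.00e- 1
#> 7 synthetic       1 cluster     SYN3      7.02e- 1
#> 8 synthetic       1 cluster     SYN4      5.04e-10

assignment_accuracy(a, sim$truth$true_signature)
#> [1] 0.94825
```

The two latent region mixtures (0.6/0.3/0.1 and 0.1/0.2/0.7) are recovered
as `K = 2` clusters with exposures within ~0.01 of truth, and 94.8% of
mutations receive their generating signature — essentially the
Bayes-optimal rate for this mixture (94.75%, `bayes_accuracy()`), since on
channels shared between signatures no assignment rule can do better than
the regional exposures.

Real data enter through `read_mutations()` (TSV/MAF/VCF, with trinucleotide
contexts taken from a reference FASTA when absent),
`read_signature_matrix()` (COSMIC-layout files, any orientation), and
`attach_signal()` / `read_signal_track()` for per-mutation covariates such
as Repli-seq.  `run_pipeline(pipeline_config(...))` chains all stages and
writes `segments.bed`, `clusters.tsv`, `assignments.tsv`, downstream
tables, and a reproducibility manifest; `inst/cli/sigsegment.R` exposes the
same pipeline as a shell command with subcommands `simulate`, `segment`,
`cluster`, `assign`, `concordance`, `kataegis`, `ks-pairs` and `run`.

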