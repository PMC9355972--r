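#' Configuration for the full analysis pipeline
#'
#' Bundles every tunable of the pipeline with defaults matching the
#' method's stated settings: BIC multipliers 5 and 5, 30 mutations per
#' initial bin, 10,000 permutations, kataegis rule (>= 6 mutations,
#' < 1000 bp), a 30,000-mutation hypermutation cap and FDR 0.05.
#'
#' @param input Mutation file path (TSV/MAF/VCF), or an existing catalog.
#' @param signatures Signature matrix path, or a V x 96 matrix.
#' @param fasta Optional reference FASTA for context extraction.
#' @param out_dir Output directory.
#' @param format,min_mutations Passed to [read_mutations()].
#' @param lambda1,lambda2,min_bin_count Passed to [seg_config()].
#' @param signature_subset Optional character vector restricting the
#'   signature matrix rows (e.g. `paste0("SBS", 1:17)`).
#' @param method Exposure method (`"em"` or `"nnls"`).
#' @param min_exposure Exposure discard threshold (default 0).
#' @param B,seed Permutation count and seed for concordance.
#' @param kataegis_min_run,kataegis_max_dist,max_mutations Kataegis rule.
#' @param fdr_alpha FDR threshold for CCF pair discordance.
#' @param stages Character vector of stages to run, in pipeline order, out
#'   of `"segment"`, `"cluster"`, `"assign"`, `"concordance"`,
#'   `"kataegis"`, `"ks_pairs"`.  Later stages require earlier ones.
#' @return A `sigseg_pipeline_config` list.
#' @export
pipeline_config <- function(input, signatures, fasta = NULL,
                            out_dir = "sigsegment_out",
                            format = "auto", min_mutations = 3000,
                            lambda1 = 5, lambda2 = 5, min_bin_count = 30L,
                            signature_subset = NULL,
                            method = "em", min_exposure = 0,
                            B = 10000L, seed = 1L,
                            kataegis_min_run = 6L,
                            kataegis_max_dist = 1000L,
                            max_mutations = 30000L,
                            fdr_alpha = 0.05,
                            stages = c("segment", "cluster", "assign")) {
  known <- c("segment", "cluster", "assign", "concordance", "kataegis",
             "ks_pairs")
  bad <- setdiff(stages, known)
  if (length(bad)) abort(paste0("unknown stage(s): ", paste(bad, collapse = ", ")))
  structure(
    list(input = input, signatures = signatures, fasta = fasta,
         out_dir = out_dir, format = format, min_mutations = min_mutations,
         config = seg_config(lambda1, lambda2, min_bin_count),
         signature_subset = signature_subset, method = method,
         min_exposure = min_exposure, B = as.integer(B),
         seed = as.integer(seed),
         kataegis_min_run = as.integer(kataegis_min_run),
         kataegis_max_dist = as.integer(kataegis_max_dist),
         max_mutations = as.integer(max_mutations),
         fdr_alpha = fdr_alpha, stages = stages),
    class = "sigseg_pipeline_config"
  )
}

#' Run the pipeline: read, segment, cluster, assign, downstream
#'
#' Chains the stages on one configuration: read the mutations and signature
#' matrix, segment each chromosome, cluster segments genome-wide, estimate
#' per-cluster exposures and assign every mutation to its
#' maximum-posterior signature, then optionally run the signal/CCF
#' concordance tests, kataegis detection with enrichment, and pairwise CCF
#' discordance.  All tabular outputs plus a JSON run manifest (package
#' version, seed, configuration hash) are written to `out_dir`; identical
#' configuration and inputs give identical outputs.
#'
#' @param cfg A [pipeline_config()].
#' @return Invisibly, a named list of the in-memory results
#'   (`catalog`, `segmentation`, `clustering`, `assignment`, and any
#'   downstream tables), with `paths` of the files written.
#' @export
run_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "sigseg_pipeline_config"))
  H <- if (is.matrix(cfg$signatures)) {
    validate_signature_matrix(cfg$signatures)
  } else {
    if (!file.exists(cfg$signatures)) {
      abort(sprintf("signature matrix not found: %s", cfg$signatures))
    }
    read_signature_matrix(cfg$signatures)
  }
  if (!is.null(cfg$signature_subset)) {
    missing_sig <- setdiff(cfg$signature_subset, rownames(H))
    if (length(missing_sig)) {
      abort(paste0("signatures not in matrix: ",
                   paste(missing_sig, collapse = ", ")))
    }
    H <- H[cfg$signature_subset, , drop = FALSE]
    H <- H / rowSums(H)
  }
  catalog <- if (is_mut_catalog(cfg$input)) cfg$input else {
    read_mutations(cfg$input, format = cfg$format, fasta = cfg$fasta,
                   min_mutations = cfg$min_mutations)
  }
  res <- list(catalog = catalog)
  st <- cfg$stages

  if ("segment" %in% st) {
    res$segmentation <- segment_catalog(catalog, cfg$config)
  }
  if ("cluster" %in% st) {
    res$clustering <- cluster_segments(res$segmentation, cfg$config)
  }
  if ("assign" %in% st) {
    res$assignment <- assign_signatures(catalog, res$clustering, H,
                                        method = cfg$method,
                                        min_exposure = cfg$min_exposure)
  }
  if ("concordance" %in% st) {
    sig_cols <- intersect(c("signal", "ccf"), names(catalog))
    res$concordance <- dplyr::bind_rows(lapply(sig_cols, function(sc) {
      dplyr::mutate(
        cluster_concordance(res$assignment, signal_col = sc,
                            B = cfg$B, seed = cfg$seed),
        signal = sc, .before = 1)
    }))
  }
  if ("kataegis" %in% st) {
    res$kataegis <- detect_kataegis(catalog, cfg$kataegis_min_run,
                                    cfg$kataegis_max_dist,
                                    cfg$max_mutations)
    if (nrow(res$kataegis) && !is.null(res$assignment)) {
      res$kataegis_enrichment <- kataegis_enrichment(res$kataegis,
                                                     res$assignment)
    }
  }
  if ("ks_pairs" %in% st) {
    res$ks_pairs <- ccf_pair_discordance(res$assignment,
                                         alpha = cfg$fdr_alpha)
  }

  if (!dir.exists(cfg$out_dir)) dir.create(cfg$out_dir, recursive = TRUE)
  paths <- write_outputs(catalog, res$segmentation, res$clustering,
                         res$assignment, cfg$out_dir)
  for (nm in intersect(c("concordance", "kataegis", "kataegis_enrichment",
                         "ks_pairs"), names(res))) {
    p <- file.path(cfg$out_dir, paste0(nm, ".tsv"))
    fmt_tsv(tibble::as_tibble(res[[nm]]), p)
    paths <- c(paths, p)
  }
  manifest <- list(
    package = "sigsegment",
    version = as.character(utils::packageVersion("sigsegment")),
    seed = cfg$seed,
    stages = cfg$stages,
    config_hash = rlang::hash(cfg[setdiff(names(cfg), "input")]),
    n_mutations = nrow(catalog),
    outputs = basename(paths)
  )
  mp <- file.path(cfg$out_dir, "manifest.json")
  jsonlite::write_json(manifest, mp, auto_unbox = TRUE, pretty = TRUE)
  res$paths <- c(paths, mp)
  invisible(res)
}
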