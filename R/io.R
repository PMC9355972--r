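#' Read somatic mutation calls into a catalog
#'
#' Supports a minimal 5-column TSV (`chrom`, `pos`, `ref`, `alt`, optional
#' `sample_id`, `context`, `ccf`, `signal`), MAF (columns `Chromosome`,
#' `Start_Position`, `Reference_Allele`, `Tumor_Seq_Allele2`,
#' `Tumor_Sample_Barcode`; extra columns ignored) and VCF (plain or
#' gzipped; multi-allelic records are split and each ALT treated
#' independently).  Non-SNV rows are skipped and counted.  If the input has
#' no trinucleotide `context` column, `fasta` must point to a reference
#' FASTA from which the flanking bases are extracted; records whose
#' reference base disagrees with the FASTA are dropped and counted.
#'
#' Samples with fewer than `min_mutations` usable SNVs are rejected (the
#' default 3000 matches the study-design floor for stable per-genome
#' signature estimation); set `min_mutations = 0` to keep everything.
#'
#' @param path Input file.
#' @param format One of `"auto"`, `"tsv"`, `"maf"`, `"vcf"`; `"auto"` guesses
#'   from the file extension.
#' @param fasta Optional reference FASTA path for context extraction.
#' @param min_mutations Minimum usable SNVs per sample (default 3000).
#' @param sample_id Sample name used when the format carries none (VCF, bare
#'   TSV); defaults to the file stem.
#' @param ccf_col,signal_col Names of optional per-mutation CCF / signal
#'   columns in TSV/MAF input.
#' @return A [as_mut_catalog()] tibble.  Attributes: `skipped` (named counts
#'   of dropped rows by reason) and `rejected_samples` (tibble of samples
#'   below `min_mutations` with their counts).
#' @export
read_mutations <- function(path, format = c("auto", "tsv", "maf", "vcf"),
                           fasta = NULL, min_mutations = 3000,
                           sample_id = NULL,
                           ccf_col = "ccf", signal_col = "signal") {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.vcf(\\.gz|\\.bgz)?$", path, ignore.case = TRUE)) {
      "vcf"
    } else if (grepl("\\.maf(\\.gz)?$", path, ignore.case = TRUE)) {
      "maf"
    } else "tsv"
  }
  default_id <- sample_id %||%
    sub("\\.(tsv|txt|maf|vcf)(\\.gz|\\.bgz)?$", "", basename(path),
        ignore.case = TRUE)
  raw <- switch(format,
    tsv = read_mutations_tsv(path, default_id, ccf_col, signal_col),
    maf = read_mutations_maf(path, ccf_col, signal_col),
    vcf = read_mutations_vcf(path, default_id)
  )
  skipped <- c(non_snv = 0L, ref_mismatch = 0L, context_unresolvable = 0L)

  snv <- grepl("^[ACGT]$", raw$ref) & grepl("^[ACGT]$", raw$alt) &
    raw$ref != raw$alt
  skipped["non_snv"] <- sum(!snv)
  raw <- raw[snv, , drop = FALSE]
  if (nrow(raw) == 0) abort("zero usable SNV records")

  if (!"context" %in% names(raw) || all(is.na(raw$context))) {
    if (is.null(fasta)) {
      abort("input carries no trinucleotide contexts; a reference `fasta` is required")
    }
    ctx <- extract_contexts(fasta, raw$chrom, raw$pos)
    mism <- !is.na(ctx) & substr(ctx, 2, 2) != raw$ref
    skipped["ref_mismatch"] <- sum(mism)
    ctx[mism] <- NA_character_
    raw$context <- ctx
  }
  unresolved <- is.na(raw$context) | !grepl("^[ACGT]{3}$", raw$context)
  skipped["context_unresolvable"] <- skipped["context_unresolvable"] +
    sum(unresolved & !is.na(raw$context)) + sum(is.na(raw$context)) -
    skipped["ref_mismatch"]
  raw <- raw[!unresolved, , drop = FALSE]
  if (nrow(raw) == 0) abort("zero usable SNV records after context resolution")
  raw$channel <- encode_context(raw$context, raw$ref, raw$alt)

  tab <- table(raw$sample_id)
  rejected <- tibble::tibble(
    sample_id = names(tab)[tab < min_mutations],
    n = as.integer(tab[tab < min_mutations])
  )
  if (nrow(rejected)) {
    warn(sprintf("rejecting %d sample(s) below min_mutations = %d: %s",
                 nrow(rejected), min_mutations,
                 paste(rejected$sample_id, collapse = ", ")))
    raw <- raw[!raw$sample_id %in% rejected$sample_id, , drop = FALSE]
  }
  if (nrow(raw) == 0) abort("zero usable records: all samples rejected")
  if (sum(skipped) > 0) {
    warn(sprintf("skipped rows: %s",
                 paste(names(skipped), skipped, sep = "=", collapse = ", ")))
  }
  out <- as_mut_catalog(raw)
  attr(out, "skipped") <- skipped
  attr(out, "rejected_samples") <- rejected
  out
}

read_mutations_tsv <- function(path, default_id, ccf_col, signal_col) {
  # all-character parse: lone T/F allele values must not become logicals
  x <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE,
                       comment = "#",
                       col_types = readr::cols(.default = "c"))
  names(x) <- tolower(names(x))
  need <- c("chrom", "pos", "ref", "alt")
  if (!all(need %in% names(x))) {
    abort(paste0("TSV must have columns ", paste(need, collapse = ", ")))
  }
  out <- tibble::tibble(
    sample_id = if ("sample_id" %in% names(x)) as.character(x$sample_id) else default_id,
    chrom = as.character(x$chrom), pos = as.integer(x$pos),
    ref = toupper(x$ref), alt = toupper(x$alt)
  )
  if ("context" %in% names(x)) out$context <- toupper(x$context)
  if (tolower(ccf_col) %in% names(x)) out$ccf <- as.numeric(x[[tolower(ccf_col)]])
  if (tolower(signal_col) %in% names(x)) out$signal <- as.numeric(x[[tolower(signal_col)]])
  out
}

read_mutations_maf <- function(path, ccf_col, signal_col) {
  x <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE,
                       comment = "#",
                       col_types = readr::cols(.default = "c"))
  need <- c("Chromosome", "Start_Position", "Reference_Allele",
            "Tumor_Seq_Allele2", "Tumor_Sample_Barcode")
  if (!all(need %in% names(x))) {
    abort(paste0("MAF must have columns ", paste(need, collapse = ", ")))
  }
  out <- tibble::tibble(
    sample_id = as.character(x$Tumor_Sample_Barcode),
    chrom = as.character(x$Chromosome),
    pos = as.integer(x$Start_Position),
    ref = toupper(x$Reference_Allele),
    alt = toupper(x$Tumor_Seq_Allele2)
  )
  if (ccf_col %in% names(x)) out$ccf <- as.numeric(x[[ccf_col]])
  if (signal_col %in% names(x)) out$signal <- as.numeric(x[[signal_col]])
  out
}

read_mutations_vcf <- function(path, default_id) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- tibble::as_tibble(as.data.frame(vcfR::getFIX(v),
                                         stringsAsFactors = FALSE))
  out <- tibble::tibble(
    sample_id = default_id,
    chrom = as.character(fix$CHROM), pos = as.integer(fix$POS),
    ref = toupper(fix$REF), alt = toupper(fix$ALT)
  )
  # split multi-allelic sites; each ALT is an independent record
  tidyr::separate_rows(out, "alt", sep = ",")
}

## Trinucleotide context around 1-based positions from a FASTA file.
## Positions at contig edges or on absent contigs yield NA.
extract_contexts <- function(fasta, chrom, pos) {
  seqs <- Biostrings::readDNAStringSet(fasta)
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  ctx <- rep(NA_character_, length(chrom))
  for (ch in unique(chrom)) {
    if (!ch %in% names(seqs)) next
    len <- length(seqs[[ch]])
    sel <- which(chrom == ch)
    ok <- sel[pos[sel] > 1L & pos[sel] < len]
    if (!length(ok)) next
    v <- Biostrings::Views(seqs[[ch]], start = pos[ok] - 1L, width = 3L)
    ctx[ok] <- toupper(as.character(v))
  }
  ctx
}

#' Read a COSMIC-style signature probability matrix
#'
#' Accepts the COSMIC Ver. 2 tab-separated layout (96 channel rows with
#' `Substitution Type` / `Trinucleotide` / `Somatic Mutation Type` columns
#' followed by one column per signature), a plain channels-by-signatures
#' table whose first column holds channel labels like `A[C>A]A`, or the
#' transposed signatures-by-channels layout; the orientation is
#' auto-detected from the labels.  Channels are re-indexed to the canonical
#' order of [sbs96_channels()].  Signature rows are renormalized when their
#' sum is within 1e-3 of 1 and rejected otherwise.
#'
#' @param path Tab-separated file.
#' @return A numeric V x 96 matrix; rownames are signature ids, colnames the
#'   canonical channel labels, each row summing to 1.
#' @export
read_signature_matrix <- function(path) {
  x <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  lab <- sbs96_channels()
  chr_cols <- names(x)[vapply(x, is.character, logical(1))]
  label_col <- NULL
  for (cc in chr_cols) {
    if (all(lab %in% x[[cc]])) { label_col <- cc; break }
  }
  if (!is.null(label_col)) {
    # channels in rows
    num <- x[, vapply(x, is.numeric, logical(1)), drop = FALSE]
    M <- t(as.matrix(num))
    colnames(M) <- x[[label_col]]
    M <- M[, lab, drop = FALSE]
  } else if (all(lab %in% names(x))) {
    # channels in columns, signatures in rows
    id_col <- if (length(chr_cols)) chr_cols[1] else NULL
    M <- as.matrix(x[, lab, drop = FALSE])
    rownames(M) <- if (!is.null(id_col)) x[[id_col]] else paste0("S", seq_len(nrow(M)))
  } else {
    abort("malformed signature matrix: cannot locate 96 canonical channel labels")
  }
  if (is.null(rownames(M)) || any(rownames(M) == "")) {
    rownames(M) <- paste0("S", seq_len(nrow(M)))
  }
  storage.mode(M) <- "double"
  if (any(M < 0)) abort("malformed signature matrix: negative entries")
  rs <- rowSums(M)
  if (any(abs(rs - 1) > 1e-3)) {
    abort(sprintf("malformed signature matrix: row sum off by > 1e-3 (worst: %.4g)",
                  max(abs(rs - 1))))
  }
  M <- M / rs
  colnames(M) <- lab
  validate_signature_matrix(M)
}

#' Validate a signature matrix
#'
#' @param H Numeric V x 96 matrix; rows sum to 1, entries nonnegative,
#'   columns in canonical channel order.
#' @return `H`, invisibly unchanged, or an error.
#' @export
validate_signature_matrix <- function(H) {
  if (!is.matrix(H) || ncol(H) != 96L) abort("signature matrix must be V x 96")
  if (nrow(H) < 1L) abort("signature matrix needs at least one signature")
  if (any(H < 0)) abort("signature matrix has negative entries")
  if (any(abs(rowSums(H) - 1) > 1e-6)) abort("signature rows must sum to 1")
  if (is.null(rownames(H))) rownames(H) <- paste0("S", seq_len(nrow(H)))
  H
}

#' Read a genomic signal track (bedGraph / bigWig)
#'
#' @param path Track file importable by `rtracklayer::import`.
#' @return Tibble with columns `chrom`, `start`, `end` (0-based half-open)
#'   and `value`, sorted and non-overlapping per chromosome.
#' @export
read_signal_track <- function(path) {
  if (!requireNamespace("rtracklayer", quietly = TRUE)) {
    abort("reading signal tracks requires the rtracklayer package")
  }
  gr <- rtracklayer::import(path)
  out <- tibble::tibble(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr),
    value = as.numeric(gr$score)
  )
  dplyr::arrange(out, .data$chrom, .data$start)
}

#' Attach per-mutation signal values from an interval track
#'
#' Each mutation takes the value of the interval covering its position;
#' mutations falling in track gaps get `NA` (they are dropped, with a count,
#' by the concordance test).
#'
#' @param catalog A mutation catalog.
#' @param track A tibble as from [read_signal_track()].
#' @return The catalog with a `signal` column.
#' @export
attach_signal <- function(catalog, track) {
  catalog <- assert_catalog(catalog)
  gr_track <- GenomicRanges::GRanges(
    track$chrom, IRanges::IRanges(track$start + 1L, track$end))
  gr_mut <- GenomicRanges::GRanges(
    catalog$chrom, IRanges::IRanges(catalog$pos, catalog$pos))
  hits <- GenomicRanges::findOverlaps(gr_mut, gr_track, select = "first")
  catalog$signal <- track$value[hits]
  catalog
}

fmt_tsv <- function(x, path) {
  readr::write_tsv(x, path, progress = FALSE)
}

#' Write pipeline outputs
#'
#' Writes `segments.bed` and `clusters.tsv` (segment spans with cluster ids,
#' BED coordinates 0-based half-open), and, when assignments are given,
#' `assignments.tsv` with one row per mutation carrying its coordinates,
#' channel, segment and cluster ids, the full posterior vector (columns
#' `p_<signature>`) and the argmax signature.  Output is byte-identical for
#' identical inputs.
#'
#' @param catalog A mutation catalog.
#' @param segmentation A [segment_catalog()] result.
#' @param clustering Optional [cluster_segments()] result.
#' @param assignments Optional [assign_signatures()] result.
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_outputs <- function(catalog, segmentation, clustering = NULL,
                          assignments = NULL, out_dir) {
  if (!dir.exists(out_dir)) {
    ok <- dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok) abort(sprintf("cannot create output directory %s", out_dir))
  }
  segs <- if (!is.null(clustering)) clustering else segmentation
  if (nrow(segs) == 0) abort("empty segmentation/clustering")
  paths <- character(0)

  bed <- tibble::tibble(
    chrom = segs$chrom,
    start = segs$start_pos - 1L,
    end = segs$end_pos,
    name = paste0(segs$sample_id, ":seg", segs$segment_id),
    score = segs$n,
    cluster_id = if ("cluster_id" %in% names(segs)) segs$cluster_id else NA_integer_
  )
  p <- file.path(out_dir, "segments.bed")
  fmt_tsv(bed, p)
  paths <- c(paths, p)

  cl <- dplyr::select(tibble::as_tibble(segs), -dplyr::any_of("counts"))
  p <- file.path(out_dir, "clusters.tsv")
  fmt_tsv(cl, p)
  paths <- c(paths, p)

  if (!is.null(assignments)) {
    p <- file.path(out_dir, "assignments.tsv")
    fmt_tsv(tibble::as_tibble(assignments), p)
    paths <- c(paths, p)
  }
  invisible(paths)
}

#' Read an assignments table written by [write_outputs()]
#'
#' @param path Path to `assignments.tsv`.
#' @return A `mut_assignment` tibble with posterior columns restored.
#' @export
read_assignments <- function(path) {
  x <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  class(x) <- c("mut_assignment", class(x))
  x
}
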