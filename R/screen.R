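#' Build peak-intersecting SNP windows for motif screening
#'
#' Enlarges each SNP position by `flank_bp` on each side (the default 100 bp
#' gives a 201 bp window including the SNP base) and keeps only SNPs whose
#' window overlaps at least one peak interval by at least 1 bp (half-open
#' intersection).  SNPs lacking ref/alt alleles are skipped with a warning.
#'
#' @param snps A SNP set (see [snp_set()]) with `ref`/`alt` columns.
#' @param peaks A `GRanges` peak track on the SNP set's genome.
#' @param flank_bp Flank added on each side of the SNP (default 100).
#' @return A `data.frame` with the retained SNP rows plus `window_start`,
#'   `window_end` (0-based half-open, clipped to chromosome bounds) and
#'   `snp_offset` (0-based offset of the SNP base inside its window).
#' @export
build_snp_windows <- function(snps, peaks, flank_bp = 100) {
  si <- .as_seqinfo(attr(snps, "genome") %||% GenomeInfoDb::seqinfo(peaks))
  .check_same_genome(si, peaks)
  if (!all(c("ref", "alt") %in% names(snps))) {
    .stopf("SNP set needs 'ref' and 'alt' allele columns for motif screening")
  }
  no_allele <- is.na(snps$ref) | is.na(snps$alt)
  if (any(no_allele)) {
    .warnf("skipped %d SNP(s) without ref/alt alleles", sum(no_allele))
    snps <- snps[!no_allele, , drop = FALSE]
  }
  if (nrow(snps) == 0L) {
    return(cbind(snps, window_start = numeric(0), window_end = numeric(0),
                 snp_offset = integer(0)))
  }
  known <- GenomeInfoDb::seqnames(si)
  lens <- as.double(GenomeInfoDb::seqlengths(si))[match(snps$chrom, known)]
  pos0 <- snps$pos - 1
  ws <- pmax(pos0 - flank_bp, 0)
  we <- pmin(pos0 + flank_bp + 1, lens)
  wgr <- GenomicRanges::GRanges(
    seqnames = factor(snps$chrom, levels = known),
    ranges = IRanges::IRanges(start = ws + 1, end = we),
    seqinfo = si)
  keep <- IRanges::overlapsAny(wgr, peaks, ignore.strand = TRUE)
  out <- snps[keep, , drop = FALSE]
  out$window_start <- ws[keep]
  out$window_end <- we[keep]
  out$snp_offset <- as.integer(pos0[keep] - ws[keep])
  rownames(out) <- NULL
  out
}

#' Screen SNPs for motif disruption
#'
#' For each SNP window, scores the window sequence carrying the reference
#' allele and the sequence carrying the alternate allele with
#' [scan_best_hit()], and reports the best-hit score difference
#' `delta = ref_score - alt_score` (positive when the variant weakens the
#' best motif match).  Each best-hit per-w-mer p-value is calibrated to a
#' sequence-level p-value with the Sidak correction for the number of
#' windows scanned, `1 - (1 - p)^n_windows`, and Benjamini-Hochberg q-values
#' are computed jointly across all ref and alt hits.  A SNP is flagged
#' significant when either allele's hit has `q < alpha`.
#'
#' @param windows Output of [build_snp_windows()].
#' @param sequences A named [Biostrings::DNAStringSet] providing the
#'   chromosome sequences, or a path to a FASTA file.
#' @param pwm A `"pwm"` object.
#' @param alpha Significance threshold on the q-value (default 0.05).
#' @return A `data.frame` with one row per screened SNP: `id`, `chrom`,
#'   `window_start`, `window_end`, `ref_score`, `alt_score`, `ref_p`,
#'   `alt_p`, `ref_q`, `alt_q`, `delta`, `significant`, `error` (NA unless
#'   sequence fetch failed for that SNP, in which case the screen continues).
#' @export
snp_disruption_screen <- function(windows, sequences, pwm, alpha = 0.05) {
  if (is.character(sequences) && length(sequences) == 1L) {
    sequences <- Biostrings::readDNAStringSet(sequences)
    names(sequences) <- sub("\\s.*$", "", names(sequences))
  }
  n <- nrow(windows)
  res <- data.frame(
    id = windows$id, chrom = windows$chrom,
    window_start = windows$window_start, window_end = windows$window_end,
    ref_score = NA_real_, alt_score = NA_real_,
    ref_p = NA_real_, alt_p = NA_real_,
    ref_q = NA_real_, alt_q = NA_real_,
    delta = NA_real_, significant = NA, error = NA_character_,
    stringsAsFactors = FALSE)
  for (i in seq_len(n)) {
    fetch <- tryCatch({
      chr <- windows$chrom[i]
      if (!chr %in% names(sequences)) .stopf("no sequence for '%s'", chr)
      s <- as.character(Biostrings::subseq(
        sequences[[chr]], windows$window_start[i] + 1, windows$window_end[i]))
      chars <- strsplit(toupper(s), "")[[1]]
      off <- windows$snp_offset[i] + 1L
      ref_chars <- replace(chars, off, windows$ref[i])
      alt_chars <- replace(chars, off, windows$alt[i])
      rh <- scan_best_hit(paste(ref_chars, collapse = ""), pwm)
      ah <- scan_best_hit(paste(alt_chars, collapse = ""), pwm)
      res$ref_score[i] <- rh$score
      res$alt_score[i] <- ah$score
      res$ref_p[i] <- .sidak(rh$p_value, rh$n_windows)
      res$alt_p[i] <- .sidak(ah$p_value, ah$n_windows)
      res$delta[i] <- rh$score - ah$score
      NULL
    }, error = function(e) conditionMessage(e))
    if (!is.null(fetch)) res$error[i] <- fetch
  }
  ok <- is.na(res$error)
  if (any(ok)) {
    pooled <- stats::p.adjust(c(res$ref_p[ok], res$alt_p[ok]), method = "BH")
    res$ref_q[ok] <- pooled[seq_len(sum(ok))]
    res$alt_q[ok] <- pooled[sum(ok) + seq_len(sum(ok))]
    res$significant[ok] <- res$ref_q[ok] < alpha | res$alt_q[ok] < alpha
  }
  res
}

# sequence-level calibration of a best-hit w-mer p-value for the number of
# windows scanned (conservative under the positive dependence of
# overlapping windows)
.sidak <- function(p, n_windows) {
  1 - (1 - p)^n_windows
}
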