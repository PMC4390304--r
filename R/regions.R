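#' Read a SNP table
#'
#' Reads a tab-separated table of point variants with header columns
#' `chrom`, `pos`, `id` and optionally `ref`, `alt`, `ld_proxy`.  Positions
#' are 1-based (the convention of GWAS catalogs and VCF); they are validated
#' against the genome here and converted to 0-based coordinates only where
#' intervals are built ([build_regions()], [build_snp_windows()]).
#'
#' @param path Path to the table.
#' @param genome A `Seqinfo` genome.
#' @return A `data.frame` with columns `chrom`, `pos`, `id` and, when
#'   present, `ref`, `alt`, `ld_proxy`; the genome is attached as the
#'   `"genome"` attribute.
#' @export
read_snp_table <- function(path, genome) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  need <- c("chrom", "pos", "id")
  miss <- setdiff(need, names(df))
  if (length(miss)) .stopf("SNP table '%s' lacks column(s): %s",
                           path, paste(miss, collapse = ", "))
  snp_set(df, genome)
}

#' Validate a SNP set against a genome
#'
#' @param df A `data.frame` with at least `chrom`, `pos` (1-based), `id`.
#'   Optional columns: `ref`, `alt` (single bases in ACGT), `ld_proxy`
#'   (logical flag for linkage-disequilibrium proxies of reported variants).
#' @param genome A `Seqinfo` genome.
#' @return The validated `data.frame` with the genome attached as an
#'   attribute.
#' @export
snp_set <- function(df, genome) {
  si <- .as_seqinfo(genome)
  df <- as.data.frame(df)
  df$chrom <- as.character(df$chrom)
  df$pos <- as.double(df$pos)
  df$id <- as.character(df$id)
  if (anyDuplicated(df$id)) .stopf("duplicated SNP id: %s",
                                   df$id[duplicated(df$id)][1])
  known <- GenomeInfoDb::seqnames(si)
  bad <- which(!(df$chrom %in% known))
  if (length(bad)) .stopf("SNP '%s' on unknown chromosome '%s'",
                          df$id[bad[1]], df$chrom[bad[1]])
  lens <- as.double(GenomeInfoDb::seqlengths(si))[match(df$chrom, known)]
  bad <- which(is.na(df$pos) | df$pos < 1 | df$pos > lens | df$pos != floor(df$pos))
  if (length(bad)) .stopf("SNP '%s' position outside chromosome bounds", df$id[bad[1]])
  for (col in c("ref", "alt")) {
    if (col %in% names(df)) {
      v <- toupper(as.character(df[[col]]))
      ok <- is.na(v) | v %in% c("A", "C", "G", "T")
      if (!all(ok)) .stopf("SNP '%s': %s allele must be one of A,C,G,T",
                           df$id[which(!ok)[1]], col)
      df[[col]] <- v
    }
  }
  if ("ld_proxy" %in% names(df)) df$ld_proxy <- as.logical(df$ld_proxy)
  attr(df, "genome") <- si
  df
}

#' Build disease-associated regions around SNPs
#'
#' Expands each SNP into the genomic interval of total width `width_bp`
#' centered on it: `[pos0 - width/2, pos0 + width/2)` with `pos0` the 0-based
#' SNP position, i.e. "SNP position +/- width/2".  Overlapping per-SNP
#' regions are merged and intervals are clipped at chromosome ends.
#'
#' @param snps A SNP set (see [snp_set()]); may carry its genome as an
#'   attribute.
#' @param width_bp Total region width in bp; a positive even integer.
#' @param genome A `Seqinfo` genome (defaults to the SNP set's own).
#' @return A normalized `GRanges` track of associated regions (empty for an
#'   empty SNP set).
#' @examples
#' g <- Genome(c(chr1 = 1e6))
#' s <- snp_set(data.frame(chrom = "chr1", pos = 500001, id = "rs1"), g)
#' build_regions(s, 100000)  # chr1:[450000, 550000)
#' @export
build_regions <- function(snps, width_bp, genome = attr(snps, "genome")) {
  si <- .as_seqinfo(genome)
  width_bp <- as.double(width_bp)
  if (length(width_bp) != 1L || is.na(width_bp) || width_bp <= 0 ||
      width_bp %% 2 != 0) {
    .stopf("width_bp must be a positive even integer")
  }
  if (nrow(snps) == 0L) return(GenomicRanges::GRanges(seqinfo = si))
  pos0 <- snps$pos - 1
  start0 <- pmax(pos0 - width_bp / 2, 0)
  end <- pos0 + width_bp / 2
  suppressWarnings(
    as_track(data.frame(chrom = snps$chrom, start = start0, end = end),
             si, normalize = TRUE, clip = TRUE))
}

#' Split two region tracks into disjoint case and control tracks
#'
#' Mutually discards shared base pairs: returns
#' `(subtract(case, control), subtract(control, case))`, so the outputs never
#' share a base pair.  With `whole_segment = TRUE` any *segment* of one track
#' that touches the other track is dropped entirely instead (the coarser
#' reading of discarding overlapping segments).
#'
#' @param case,control `GRanges` tracks on the same genome.
#' @param whole_segment Drop whole touching segments instead of subtracting
#'   at base-pair resolution (default `FALSE`).
#' @return A list with elements `case` and `control`, bp-disjoint tracks.
#' @export
split_case_control <- function(case, control, whole_segment = FALSE) {
  .check_same_genome(case, control)
  if (whole_segment) {
    hit_c <- IRanges::overlapsAny(case, control, ignore.strand = TRUE)
    hit_k <- IRanges::overlapsAny(control, case, ignore.strand = TRUE)
    return(list(case = case[!hit_c], control = control[!hit_k]))
  }
  list(case = subtract_tracks(case, control),
       control = subtract_tracks(control, case))
}
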