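#' Build a track from interval coordinates
#'
#' A *track* is a set of genomic intervals on a fixed genome, stored as an
#' unstranded [GenomicRanges::GRanges] whose `seqinfo` is the genome.  In
#' normalized form the intervals are sorted, pairwise non-overlapping and
#' non-adjacent (overlapping or book-ended intervals are merged), which is the
#' canonical representation for base-pair occupancy statistics.
#'
#' Coordinates follow the BED convention: 0-based, half-open `[start, end)`.
#' Internally they are held 1-based (the GRanges convention); conversion
#' happens here and in [read_bed()]/[write_bed()] only.
#'
#' @param x A `data.frame` with columns `chrom`, `start`, `end` (0-based
#'   half-open), or a `GRanges`.
#' @param genome A `Seqinfo` genome (see [Genome()]).  Required for data
#'   frames; for a `GRanges` input defaults to its own `seqinfo`.
#' @param normalize Merge overlapping/adjacent intervals and sort
#'   (default `TRUE`).
#' @param clip Clip intervals extending past chromosome ends instead of
#'   erroring (default `TRUE`, with a warning).
#' @return A `GRanges` track.
#' @examples
#' g <- Genome(c(chr1 = 1000))
#' as_track(data.frame(chrom = "chr1", start = c(50, 100), end = c(150, 250)), g)
#' @export
as_track <- function(x, genome = NULL, normalize = TRUE, clip = TRUE) {
  if (methods::is(x, "GRanges")) {
    si <- if (is.null(genome)) GenomeInfoDb::seqinfo(x) else .as_seqinfo(genome)
    df <- data.frame(chrom = as.character(GenomicRanges::seqnames(x)),
                     start = GenomicRanges::start(x) - 1,
                     end = GenomicRanges::end(x))
    return(as_track(df, si, normalize = normalize, clip = clip))
  }
  si <- .as_seqinfo(genome)
  chrom <- as.character(x$chrom)
  start0 <- as.double(x$start)
  end <- as.double(x$end)
  known <- GenomeInfoDb::seqnames(si)
  bad <- which(!(chrom %in% known))
  if (length(bad)) .stopf("unknown chromosome '%s' (interval %d)", chrom[bad[1]], bad[1])
  if (anyNA(start0) || anyNA(end)) .stopf("NA interval coordinates")
  if (any(start0 < 0)) .stopf("negative start coordinate")
  if (any(start0 >= end)) .stopf("interval with start >= end")
  lens <- as.double(GenomeInfoDb::seqlengths(si))[match(chrom, known)]
  over <- end > lens
  if (any(over)) {
    if (!clip) .stopf("%d interval(s) extend past chromosome end", sum(over))
    .warnf("clipped %d interval(s) to chromosome bounds", sum(over))
    end <- pmin(end, lens)
    keep <- start0 < end
    chrom <- chrom[keep]; start0 <- start0[keep]; end <- end[keep]
  }
  gr <- GenomicRanges::GRanges(
    seqnames = factor(chrom, levels = known),
    ranges = IRanges::IRanges(start = start0 + 1, end = end),
    seqinfo = si)
  if (normalize) normalize_track(gr) else sort(gr)
}

#' Normalize a track
#'
#' Sorts intervals and merges any that overlap or are book-ended, yielding the
#' canonical form in which consecutive intervals on a chromosome are separated
#' by at least 1 bp.  Normalization is idempotent and leaves base-pair
#' coverage unchanged for already-disjoint input.
#'
#' @param track A `GRanges` track.
#' @return A normalized `GRanges` track.
#' @export
normalize_track <- function(track) {
  sort(GenomicRanges::reduce(track, ignore.strand = TRUE))
}

#' Base pairs covered by a track
#'
#' @param track A `GRanges` track (normalized; for raw interval sets the
#'   result counts multiply-covered base pairs multiple times).
#' @return Numeric scalar, total covered base pairs.
#' @export
coverage_bp <- function(track) {
  sum(as.double(GenomicRanges::width(track)))
}

#' Read a BED file as a track
#'
#' Reads 3+-column tab-separated BED (browser/track/comment lines skipped,
#' columns beyond the third ignored) into a normalized track on `genome`.
#' Malformed lines raise an error naming the offending line number.
#'
#' @param path Path to a BED3+ file.
#' @param genome A `Seqinfo` genome.
#' @param normalize Merge overlapping/adjacent intervals (default `TRUE`).
#' @param strict If `TRUE` (default) a line on a chromosome absent from
#'   `genome` is an error; if `FALSE` such lines are skipped with a warning.
#' @return A `GRanges` track.
#' @export
read_bed <- function(path, genome, normalize = TRUE, strict = TRUE) {
  si <- .as_seqinfo(genome)
  lines <- readLines(path, warn = FALSE)
  lineno <- seq_along(lines)
  skip <- grepl("^(#|track\\b|browser\\b)", lines) | !nzchar(trimws(lines))
  lines <- lines[!skip]; lineno <- lineno[!skip]
  if (length(lines) == 0L) {
    return(GenomicRanges::GRanges(seqinfo = si))
  }
  parts <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(parts)
  if (any(nf < 3L)) {
    .stopf("%s line %d: fewer than 3 tab-separated fields", path, lineno[which(nf < 3L)[1]])
  }
  chrom <- vapply(parts, `[[`, "", 1L)
  s_chr <- vapply(parts, `[[`, "", 2L)
  e_chr <- vapply(parts, `[[`, "", 3L)
  start0 <- suppressWarnings(as.double(s_chr))
  end <- suppressWarnings(as.double(e_chr))
  bad <- which(is.na(start0) | is.na(end) |
               start0 != floor(start0) | end != floor(end))
  if (length(bad)) .stopf("%s line %d: non-integer coordinates", path, lineno[bad[1]])
  bad <- which(start0 < 0 | start0 >= end)
  if (length(bad)) .stopf("%s line %d: requires 0 <= start < end", path, lineno[bad[1]])
  unknown <- !(chrom %in% GenomeInfoDb::seqnames(si))
  if (any(unknown)) {
    if (strict) {
      .stopf("%s line %d: chromosome '%s' not in genome",
             path, lineno[which(unknown)[1]], chrom[which(unknown)[1]])
    }
    .warnf("%s: skipped %d line(s) on chromosomes not in genome", path, sum(unknown))
    chrom <- chrom[!unknown]; start0 <- start0[!unknown]; end <- end[!unknown]
  }
  if (length(chrom) == 0L) return(GenomicRanges::GRanges(seqinfo = si))
  as_track(data.frame(chrom = chrom, start = start0, end = end),
           si, normalize = normalize)
}

#' Write a track as BED3
#'
#' Coordinates are written 0-based half-open.  `read_bed(write_bed(t))`
#' round-trips any normalized track exactly.
#'
#' @param track A `GRanges` track.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_bed <- function(track, path) {
  if (length(track) == 0L) {
    writeLines(character(0), path)
    return(invisible(path))
  }
  lines <- sprintf("%s\t%.0f\t%.0f",
                   as.character(GenomicRanges::seqnames(track)),
                   as.double(GenomicRanges::start(track)) - 1,
                   as.double(GenomicRanges::end(track)))
  writeLines(lines, path)
  invisible(path)
}

#' Base-pair intersection of two tracks
#'
#' @param a,b `GRanges` tracks on the same genome.
#' @return The normalized track of base pairs covered by both `a` and `b`.
#' @export
intersect_tracks <- function(a, b) {
  .check_same_genome(a, b)
  sort(GenomicRanges::intersect(a, b, ignore.strand = TRUE))
}

#' Base-pair subtraction of two tracks
#'
#' Returns the base pairs of `a` not covered by `b`; together with
#' [intersect_tracks()] this partitions `a`:
#' `coverage_bp(subtract) + coverage_bp(intersect) == coverage_bp(a)`.
#'
#' @param a,b `GRanges` tracks on the same genome.
#' @return A normalized `GRanges` track.
#' @export
subtract_tracks <- function(a, b) {
  .check_same_genome(a, b)
  sort(GenomicRanges::setdiff(a, b, ignore.strand = TRUE))
}

#' Fraction of a track's base pairs covered by another track
#'
#' The bp-level joint-occupancy fraction: what share of `a`'s covered base
#' pairs also lie under `b`.
#'
#' @param a,b `GRanges` tracks on the same genome; `a` must be non-empty.
#' @return A fraction in `[0, 1]`.
#' @export
overlap_fraction <- function(a, b) {
  .check_same_genome(a, b)
  ca <- coverage_bp(a)
  if (ca == 0) .stopf("overlap_fraction() undefined for an empty track 'a'")
  coverage_bp(intersect_tracks(a, b)) / ca
}
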