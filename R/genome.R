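#' Define a genome from named chromosome lengths
#'
#' A genome is the coordinate universe for all tracks: an ordered set of
#' uniquely named chromosomes with positive lengths in base pairs.  It is
#' represented as a [GenomeInfoDb::Seqinfo] object, the standard Bioconductor
#' container for chromosome metadata, so tracks built on it interoperate with
#' the whole GenomicRanges ecosystem.
#'
#' @param lengths Named numeric vector of chromosome lengths (bp).  Names are
#'   chromosome names and must be unique; lengths must be positive integers
#'   below 2^31 - 1 (a GRanges representation limit; total genome size may be
#'   larger and is accumulated in double precision).
#' @return A `Seqinfo` object.
#' @examples
#' g <- Genome(c(chr1 = 1e6, chr2 = 5e5))
#' genome_size(g)
#' @seealso [read_chrom_sizes()], [genome_size()]
#' @export
Genome <- function(lengths) {
  nm <- names(lengths)
  if (is.null(nm) || any(nm == "") || anyNA(nm)) {
    .stopf("chromosome lengths must be a named vector")
  }
  if (anyDuplicated(nm)) .stopf("duplicated chromosome names: %s",
                                paste(unique(nm[duplicated(nm)]), collapse = ", "))
  len <- as.double(lengths)
  if (anyNA(len) || any(len <= 0) || any(len != floor(len))) {
    .stopf("chromosome lengths must be positive integers")
  }
  if (any(len >= 2^31)) {
    .stopf("chromosome lengths must be < 2^31 - 1 bp")
  }
  GenomeInfoDb::Seqinfo(seqnames = nm, seqlengths = as.integer(len))
}

#' Read a chromosome-sizes file
#'
#' Parses the conventional two-column `name<TAB>length` file (as produced by
#' `samtools faidx` / UCSC `fetchChromSizes`).
#'
#' @param path Path to a tab-separated file with two columns and no header.
#' @return A `Seqinfo` genome (see [Genome()]).
#' @export
read_chrom_sizes <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) .stopf("chromosome sizes file '%s' is empty", path)
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(parts) < 2L)
  if (length(bad)) .stopf("line %d of '%s': expected 'name<TAB>length'", bad[1], path)
  nm <- vapply(parts, `[[`, "", 1L)
  len <- suppressWarnings(as.double(vapply(parts, `[[`, "", 2L)))
  bad <- which(is.na(len))
  if (length(bad)) .stopf("line %d of '%s': non-numeric length", bad[1], path)
  Genome(stats::setNames(len, nm))
}

#' Total genome size in base pairs
#'
#' @param genome A `Seqinfo` genome or any object carrying one (e.g. a track).
#' @return Numeric scalar, the sum of chromosome lengths.
#' @export
genome_size <- function(genome) {
  si <- .as_seqinfo(genome)
  sum(as.double(GenomeInfoDb::seqlengths(si)))
}

.as_seqinfo <- function(x) {
  if (methods::is(x, "Seqinfo")) return(x)
  if (methods::is(x, "GRanges")) return(GenomeInfoDb::seqinfo(x))
  .stopf("expected a Seqinfo genome or a GRanges track")
}

# error unless two tracks/genomes share an identical coordinate universe
.check_same_genome <- function(a, b) {
  sa <- .as_seqinfo(a)
  sb <- .as_seqinfo(b)
  if (!identical(GenomeInfoDb::seqnames(sa), GenomeInfoDb::seqnames(sb)) ||
      !identical(GenomeInfoDb::seqlengths(sa), GenomeInfoDb::seqlengths(sb))) {
    .stopf("tracks are defined on different genomes")
  }
  invisible(sa)
}
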