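# ---- internal geometry -----------------------------------------------------
#
# The Monte Carlo engine works on linearized coordinates: chromosomes are laid
# end to end and every interval becomes [start, end) on a single double axis.
# This lets one findInterval() call compute overlap against a fixed track for
# all permuted segments of all chromosomes at once.

# chromosome offsets on the linear axis
.chrom_offsets <- function(si) {
  lens <- as.double(GenomeInfoDb::seqlengths(si))
  c(0, cumsum(lens))[seq_along(lens)]
}

# decompose a track into per-chromosome segment lengths and gap lengths
# (gaps include the flanks to the chromosome ends: n segments => n+1 gaps)
.track_layout <- function(track, si = GenomeInfoDb::seqinfo(track)) {
  chroms <- GenomeInfoDb::seqnames(si)
  lens <- as.double(GenomeInfoDb::seqlengths(si))
  offs <- .chrom_offsets(si)
  chr_of <- as.integer(GenomicRanges::seqnames(track))
  s0 <- as.double(GenomicRanges::start(track)) - 1
  e0 <- as.double(GenomicRanges::end(track))
  per <- vector("list", length(chroms))
  for (k in seq_along(chroms)) {
    idx <- which(chr_of == k)
    if (length(idx) == 0L) {
      per[[k]] <- NULL
      next
    }
    idx <- idx[order(s0[idx])]
    s <- s0[idx]; e <- e0[idx]
    per[[k]] <- list(
      lengths = e - s,
      gaps = c(s, lens[k]) - c(0, e),   # n+1 gaps, each >= 0
      offset = offs[k])
  }
  list(per = per, offsets = offs, chrom_lens = lens, si = si)
}

# one permutation draw under the current RNG state: independently permute the
# segment-length and gap-length multisets of each chromosome and lay them out
# alternately from the chromosome start (gap, segment, gap, ...).
.permute_layout <- function(layout) {
  starts <- ends <- vector("list", length(layout$per))
  for (k in seq_along(layout$per)) {
    pc <- layout$per[[k]]
    if (is.null(pc)) next
    n <- length(pc$lengths)
    L <- pc$lengths[sample.int(n)]
    g <- pc$gaps[sample.int(n + 1L)]
    st <- cumsum(g[seq_len(n)]) + c(0, cumsum(L))[seq_len(n)]
    starts[[k]] <- st + pc$offset
    ends[[k]] <- st + L + pc$offset
  }
  list(starts = unlist(starts, use.names = FALSE) %||% numeric(0),
       ends = unlist(ends, use.names = FALSE) %||% numeric(0))
}

# precompute the boundary/cumulative-coverage structure of a fixed track so
# overlap with arbitrary segment sets costs one findInterval() pass
.fixed_cov <- function(track, si = GenomeInfoDb::seqinfo(track)) {
  offs <- .chrom_offsets(si)
  chr_of <- as.integer(GenomicRanges::seqnames(track))
  s <- as.double(GenomicRanges::start(track)) - 1 + offs[chr_of]
  e <- as.double(GenomicRanges::end(track)) + offs[chr_of]
  o <- order(s)
  s <- s[o]; e <- e[o]
  w <- e - s
  list(bnd = as.vector(rbind(s, e)),      # sorted: s1 < e1 <= s2 < e2 ...
       covW = c(0, cumsum(w)))            # coverage before segment i starts
}

# covered bp of the fixed track in [0, x) for a vector of linear positions x
.cov_before <- function(x, fc) {
  j <- findInterval(x, fc$bnd)
  res <- numeric(length(x))
  inside <- j %% 2L == 1L
  if (any(inside)) {
    k <- (j[inside] + 1L) %/% 2L
    res[inside] <- fc$covW[k] + (x[inside] - fc$bnd[j[inside]])
  }
  out <- !inside & j > 0L
  if (any(out)) res[out] <- fc$covW[j[out] %/% 2L + 1L]
  res
}

# total overlap bp between segments [starts, ends) and the fixed track
.overlap_with_fixed <- function(starts, ends, fc) {
  if (length(starts) == 0L || length(fc$bnd) == 0L) return(0)
  sum(.cov_before(ends, fc)) - sum(.cov_before(starts, fc))
}

# linear segment coordinates back to a GRanges on the genome
.segments_to_track <- function(starts, ends, si) {
  if (length(starts) == 0L) return(GenomicRanges::GRanges(seqinfo = si))
  offs <- .chrom_offsets(si)
  k <- findInterval(starts, c(offs, sum(as.double(GenomeInfoDb::seqlengths(si)))))
  gr <- GenomicRanges::GRanges(
    seqnames = factor(GenomeInfoDb::seqnames(si)[k],
                      levels = GenomeInfoDb::seqnames(si)),
    ranges = IRanges::IRanges(start = starts - offs[k] + 1,
                              end = ends - offs[k]),
    seqinfo = si)
  sort(gr)
}

# ---- global permutation null ----------------------------------------------

#' Randomize a track preserving segment lengths and gaps
#'
#' Draws one sample from the global permutation null model: on each
#' chromosome the multiset of segment lengths and the multiset of
#' inter-segment gap lengths (including the flanking gaps to the chromosome
#' ends) are kept exactly, while the order of segments and the order of gaps
#' are independently randomly permuted and laid out alternately from the
#' chromosome start.  Segments never move between chromosomes.
#'
#' @param track A normalized `GRanges` track.
#' @param seed RNG seed; the draw is deterministic given the seed.
#' @return A `GRanges` track with identical per-chromosome segment-length and
#'   gap-length multisets.  The output is sorted but deliberately *not*
#'   re-normalized: a zero-length flanking gap permuted between two segments
#'   legitimately yields book-ended segments.
#' @examples
#' g <- Genome(c(chr1 = 1000))
#' t <- as_track(data.frame(chrom = "chr1", start = c(100, 400), end = c(200, 450)), g)
#' permute_track_global(t, seed = 7)
#' @export
permute_track_global <- function(track, seed) {
  si <- GenomeInfoDb::seqinfo(track)
  layout <- .track_layout(track, si)
  set.seed(seed)
  segs <- .permute_layout(layout)
  .segments_to_track(segs$starts, segs$ends, si)
}

# ---- confounder-restricted null -------------------------------------------

# sampling structure over a set of linear intervals: for a segment of length
# L, a "legal start" is any position such that the segment fits entirely
# inside one interval; legal starts are sampled uniformly across intervals.
.interval_sampler <- function(starts, ends) {
  w <- ends - starts
  o <- order(w)
  list(sw = w[o], ss = starts[o], csum = cumsum(w[o]), n = length(w))
}

# uniform draw among all legal starts for length L; NA if the segment fits in
# no interval.  Uses the current RNG state (one runif per call).
.draw_legal_start <- function(L, smp) {
  idx <- findInterval(L - 0.5, smp$sw)     # intervals with width < L
  k <- smp$n - idx
  if (k == 0L) return(NA_real_)
  base <- if (idx == 0L) 0 else smp$csum[idx]
  total <- (smp$csum[smp$n] - base) - k * (L - 1)
  u <- floor(stats::runif(1) * total)
  if (u >= total) u <- total - 1          # guard against runif(1) == 1
  # binary search for smallest j in (idx, n] with C(j) > u,
  # C(j) = sum of legal starts over intervals idx+1 .. j
  lo <- idx + 1L; hi <- smp$n
  while (lo < hi) {
    mid <- (lo + hi) %/% 2L
    Cm <- (smp$csum[mid] - base) - (mid - idx) * (L - 1)
    if (Cm > u) hi <- mid else lo <- mid + 1L
  }
  j <- lo
  Cprev <- if (j == idx + 1L) 0 else (smp$csum[j - 1L] - base) - (j - 1L - idx) * (L - 1)
  smp$ss[j] + (u - Cprev)
}

# does [s, e) overlap any occupied segment?
.occ_hits <- function(s, e, occ) {
  n <- length(occ$starts)
  if (n == 0L) return(FALSE)
  j <- findInterval(s, occ$starts)
  (j >= 1L && occ$ends[j] > s) || (j < n && occ$starts[j + 1L] < e)
}

.occ_insert <- function(s, e, occ) {
  j <- findInterval(s, occ$starts)
  occ$starts <- append(occ$starts, s, after = j)
  occ$ends <- append(occ$ends, e, after = j)
  occ
}

# place segments (longest first) uniformly among legal starts in `smp`,
# resolving collisions by rejection-resampling; fall back to genome-wide
# placement (`gsmp`) after `retry_cap` failures or when a segment fits in no
# confounder interval.  Uses the current RNG state.
.place_restricted <- function(lengths, smp, gsmp, retry_cap = 1000L) {
  ord <- order(lengths, decreasing = TRUE)
  n <- length(lengths)
  starts <- numeric(n)
  occ <- list(starts = numeric(0), ends = numeric(0))
  n_unplaceable <- 0L
  n_fallback <- 0L
  for (i in ord) {
    L <- lengths[i]
    placed <- FALSE
    fits <- smp$n > 0L && smp$sw[smp$n] >= L
    if (!fits) n_unplaceable <- n_unplaceable + 1L
    for (stage in if (fits) c("conf", "genome") else "genome") {
      this <- if (stage == "conf") smp else gsmp
      for (try in seq_len(retry_cap)) {
        s <- .draw_legal_start(L, this)
        if (is.na(s)) break
        if (!.occ_hits(s, s + L, occ)) {
          starts[i] <- s
          occ <- .occ_insert(s, s + L, occ)
          placed <- TRUE
          break
        }
      }
      if (placed) break
      if (stage == "conf") n_fallback <- n_fallback + 1L
    }
    if (!placed) {
      .stopf("restricted placement failed: segment of %d bp found no free position", L)
    }
  }
  list(starts = starts, ends = starts + lengths,
       n_unplaceable = n_unplaceable, n_fallback = n_fallback)
}

# confounder + genome sampling structures shared across MC samples
.restricted_prep <- function(confounder, si) {
  if (length(confounder) == 0L) .stopf("confounder track is empty")
  offs <- .chrom_offsets(si)
  chr_of <- as.integer(GenomicRanges::seqnames(confounder))
  cs <- as.double(GenomicRanges::start(confounder)) - 1 + offs[chr_of]
  ce <- as.double(GenomicRanges::end(confounder)) + offs[chr_of]
  lens <- as.double(GenomeInfoDb::seqlengths(si))
  list(smp = .interval_sampler(cs, ce),
       gsmp = .interval_sampler(offs, offs + lens))
}

#' Randomize a track within a confounder track
#'
#' Draws one sample from the confounder-restricted null model: every segment
#' is re-placed uniformly at random among all start positions at which it
#' lies entirely within some confounder interval (e.g. open-chromatin DHS
#' regions), preserving the segment-length multiset.  Segments that fit in no
#' confounder interval are placed uniformly genome-wide and counted in the
#' `n_unplaceable` attribute.  Collisions between placed segments are
#' resolved by rejection-resampling (cap `retry_cap` per segment, then
#' genome-wide fallback with a warning), so the output is a valid track.
#'
#' @param track A normalized `GRanges` track.
#' @param confounder A non-empty `GRanges` track on the same genome.
#' @param seed RNG seed.
#' @param retry_cap Rejection-resampling attempts per segment (default 1000).
#' @return A `GRanges` track with the same segment-length multiset as the
#'   input; attributes `n_unplaceable` (segments too long for every
#'   confounder interval) and `n_fallback` (segments placed genome-wide after
#'   exhausting retries) carry placement diagnostics.
#' @export
permute_track_restricted <- function(track, confounder, seed, retry_cap = 1000L) {
  si <- .check_same_genome(track, confounder)
  prep <- .restricted_prep(confounder, si)
  lengths <- as.double(GenomicRanges::width(track))
  set.seed(seed)
  pl <- .place_restricted(lengths, prep$smp, prep$gsmp, retry_cap)
  if (pl$n_unplaceable > 0L) {
    .warnf("%d segment(s) fit no confounder interval; placed genome-wide",
           pl$n_unplaceable)
  }
  if (pl$n_fallback > 0L) {
    .warnf("%d segment(s) fell back to genome-wide placement after %d retries",
           pl$n_fallback, retry_cap)
  }
  out <- .segments_to_track(pl$starts, pl$ends, si)
  attr(out, "n_unplaceable") <- pl$n_unplaceable
  attr(out, "n_fallback") <- pl$n_fallback
  out
}
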