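#' Peak-centered density profile
#'
#' Histogram of query-peak positions relative to anchor-peak centers, the
#' standard co-occupancy diagnostic: when two factors bind the same sites the
#' profile shows a sharp central peak, while independent factors give a flat
#' profile.  For every anchor-interval midpoint, each query-interval midpoint
#' within `window_bp` contributes one count to the bin of its signed offset
#' (query minus anchor); bins are half-open `[lo, lo + bin_bp)` spanning
#' `[-window_bp, window_bp)`.
#'
#' Midpoints are computed by integer floor division,
#' `(start + end) %/% 2` on 0-based half-open coordinates.
#'
#' @param anchors Non-empty `GRanges` track providing the centering positions.
#' @param query `GRanges` track whose midpoints are histogrammed.
#' @param window_bp Half-width of the window around each anchor (default
#'   2000 bp).
#' @param bin_bp Bin width in bp (default 25); must divide `window_bp`.
#' @return An object of class `"profile_histogram"`: `window_bp`, `bin_bp`,
#'   `bin_edges` (length `2*window_bp/bin_bp + 1`), `counts`, `n_anchors`.
#' @export
peak_centered_profile <- function(anchors, query, window_bp = 2000, bin_bp = 25) {
  .check_same_genome(anchors, query)
  if (length(anchors) == 0L) .stopf("anchor track is empty")
  window_bp <- as.double(window_bp); bin_bp <- as.double(bin_bp)
  if (window_bp <= 0 || bin_bp <= 0 || window_bp %% bin_bp != 0) {
    .stopf("window_bp must be a positive multiple of bin_bp")
  }
  si <- GenomeInfoDb::seqinfo(anchors)
  offs <- .chrom_offsets(si)
  mid <- function(gr) {
    k <- as.integer(GenomicRanges::seqnames(gr))
    s0 <- as.double(GenomicRanges::start(gr)) - 1
    e0 <- as.double(GenomicRanges::end(gr))
    sort((s0 + e0) %/% 2 + offs[k])
  }
  am <- mid(anchors)
  qm <- mid(query)
  nbins <- as.integer(2 * window_bp / bin_bp)
  counts <- integer(nbins)
  if (length(qm) > 0L) {
    for (m in am) {
      i1 <- findInterval(m - window_bp - 0.5, qm) + 1L
      i2 <- findInterval(m + window_bp - 0.5, qm)
      if (i2 < i1) next
      d <- qm[i1:i2] - m                      # offsets in [-window, window)
      counts <- counts + tabulate((d + window_bp) %/% bin_bp + 1, nbins)
    }
  }
  structure(list(
    window_bp = window_bp,
    bin_bp = bin_bp,
    bin_edges = seq(-window_bp, window_bp, by = bin_bp),
    counts = counts,
    n_anchors = length(am)
  ), class = "profile_histogram")
}

#' @export
print.profile_histogram <- function(x, ...) {
  cat(sprintf("Peak-centered profile: %d anchors, window +/-%.0f bp, %d bins of %.0f bp\n",
              x$n_anchors, x$window_bp, length(x$counts), x$bin_bp))
  ctr <- which.max(x$counts)
  cat(sprintf("  total counts %d; max bin [%.0f, %.0f) with %d\n",
              sum(x$counts), x$bin_edges[ctr], x$bin_edges[ctr + 1], x$counts[ctr]))
  invisible(x)
}

#' @describeIn peak_centered_profile Barplot of the profile (base graphics).
#' @param x A `"profile_histogram"`.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.profile_histogram <- function(x, ...) {
  centers <- x$bin_edges[-length(x$bin_edges)] + x$bin_bp / 2
  graphics::plot(centers, x$counts, type = "h", lwd = 2,
                 xlab = "offset from anchor midpoint (bp)",
                 ylab = "query midpoints per bin", ...)
  graphics::abline(v = 0, lty = 2, col = "grey50")
  invisible(x)
}

#' Export a profile histogram as a two-column table
#'
#' @param x A `"profile_histogram"`.
#' @return A `data.frame` with `bin_center_offset` and `count`.
#' @export
profile_table <- function(x) {
  data.frame(
    bin_center_offset = x$bin_edges[-length(x$bin_edges)] + x$bin_bp / 2,
    count = x$counts)
}
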