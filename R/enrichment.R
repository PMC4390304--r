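#' Observed-vs-expected overlap ratio between two tracks
#'
#' The O/E statistic: the per-bp coverage density of track `a` inside the
#' segments of track `b`, divided by its density outside them.
#' `O/E = (|a intersect b| / |b|) / ((|a| - |a intersect b|) / (G - |b|))`
#' with `G` the genome size.  `O/E = 1` means no association; values above 1
#' mean `a` preferentially covers `b`'s segments.  With
#' `denominator = "genome"` the expected density is `|a| / G` instead (the
#' marginal-density alternative).
#'
#' @param a,b `GRanges` tracks on the same genome; `a` must be non-empty and
#'   `b` must cover more than 0 and less than all of the genome.
#' @param denominator `"outside"` (default) compares inside density to the
#'   density outside `b`; `"genome"` compares it to `a`'s genome-wide density.
#' @return A list with `inside_density`, `outside_density`, `oe`
#'   (`+Inf` when `a` lies entirely inside `b`).
#' @examples
#' g <- Genome(c(chr1 = 1000))
#' b <- as_track(data.frame(chrom = "chr1", start = 0, end = 200), g)
#' a <- as_track(data.frame(chrom = "chr1", start = c(50, 600), end = c(150, 700)), g)
#' oe_ratio(a, b)  # inside 0.5, outside 0.125, oe 4
#' @export
oe_ratio <- function(a, b, denominator = c("outside", "genome")) {
  denominator <- match.arg(denominator)
  si <- .check_same_genome(a, b)
  G <- genome_size(si)
  cov_a <- coverage_bp(a)
  cov_b <- coverage_bp(b)
  if (cov_a == 0) .stopf("O/E undefined: track 'a' is empty")
  if (cov_b == 0) .stopf("O/E undefined: track 'b' is empty")
  if (cov_b >= G) .stopf("O/E undefined: track 'b' covers the whole genome")
  ov <- coverage_bp(intersect_tracks(a, b))
  .oe_from_counts(ov, cov_a, cov_b, G, denominator)
}

# O/E from raw bp counts (shared with the MC engine)
.oe_from_counts <- function(ov, cov_a, cov_b, G, denominator = "outside") {
  inside <- ov / cov_b
  outside <- (cov_a - ov) / (G - cov_b)
  expected <- if (denominator == "outside") outside else cov_a / G
  oe <- if (expected > 0) inside / expected else if (inside > 0) Inf else NaN
  list(inside_density = inside, outside_density = outside, oe = oe)
}

# null-sample summary reported with every Monte Carlo result
.null_summary <- function(stats) {
  qs <- stats::quantile(stats, c(0, 0.25, 0.5, 0.75, 0.95, 0.99, 1),
                        names = FALSE)
  list(mean = mean(stats), sd = stats::sd(stats),
       quantiles = stats::setNames(qs, c("min", "q25", "median", "q75",
                                         "q95", "q99", "max")))
}

#' Monte Carlo permutation test of overlap enrichment
#'
#' Tests whether track `a` covers track `b`'s segments more than expected
#' under a permutation null model in which `a`'s segments are randomly
#' re-placed while `b` stays fixed.  The test statistic is the observed
#' overlap in base pairs, which is a monotone transform of the O/E ratio when
#' `a`'s total coverage is preserved.  Two null models are available:
#' `"global"` ([permute_track_global()]: per-chromosome segment-length and
#' gap multisets preserved exactly) and `"restricted"`
#' ([permute_track_restricted()]: placements confined to a confounder track,
#' conditioning the test on e.g. chromatin accessibility).
#'
#' The empirical p-value uses the add-one convention
#' `p = (n_ge + 1) / (n_samples + 1)` where `n_ge` counts null samples with
#' statistic at or above the observed value.  When no null sample reaches the
#' observed statistic the result is additionally an upper bound, reported as
#' `p < 1/n_samples` (`p_is_upper_bound = TRUE`, `p_bound = 1/n_samples`);
#' with the default 50,000 samples that bound is `p < 2e-05`.
#'
#' @param a Query track whose placement is randomized.
#' @param b Target track, kept fixed.
#' @param n_samples Number of Monte Carlo null samples (default 50,000; 1,000
#'   is a practical default for the costlier restricted null).
#' @param null_mode `"global"` or `"restricted"`.
#' @param confounder Confounder track, required for the restricted null.
#' @param seed Master RNG seed; sample `i` uses `derive_seed(seed, i)`, so
#'   each null draw equals the corresponding `permute_track_*()` call.
#' @param denominator Passed to [oe_ratio()].
#' @param retry_cap Passed to the restricted placement (see
#'   [permute_track_restricted()]).
#' @return An object of class `"enrichment_result"`: observed overlap bp,
#'   inside/outside densities, `oe`, `n_samples`, `n_ge`, `p_value`,
#'   `p_is_upper_bound`, `p_bound`, `seed`, `null_mode`, a null-sample
#'   summary, and placement diagnostics for the restricted null.
#' @export
mc_enrichment_test <- function(a, b, n_samples = 50000,
                               null_mode = c("global", "restricted"),
                               confounder = NULL, seed = 1,
                               denominator = c("outside", "genome"),
                               retry_cap = 1000L) {
  null_mode <- match.arg(null_mode)
  denominator <- match.arg(denominator)
  si <- .check_same_genome(a, b)
  n_samples <- as.integer(n_samples)
  if (is.na(n_samples) || n_samples < 1L) .stopf("n_samples must be >= 1")
  if (null_mode == "restricted") {
    if (is.null(confounder)) .stopf("restricted null requires a confounder track")
    .check_same_genome(a, confounder)
  }
  G <- genome_size(si)
  cov_a <- coverage_bp(a)
  cov_b <- coverage_bp(b)
  observed <- coverage_bp(intersect_tracks(a, b))
  dens <- .oe_from_counts(observed, cov_a, cov_b, G, denominator)

  fc <- .fixed_cov(b, si)
  stats <- numeric(n_samples)
  n_unplaceable <- 0L
  n_fallback <- 0L
  if (null_mode == "global") {
    layout <- .track_layout(a, si)
    for (i in seq_len(n_samples)) {
      set.seed(derive_seed(seed, i))
      segs <- .permute_layout(layout)
      stats[i] <- .overlap_with_fixed(segs$starts, segs$ends, fc)
    }
  } else {
    prep <- .restricted_prep(confounder, si)
    lens <- as.double(GenomicRanges::width(a))
    for (i in seq_len(n_samples)) {
      set.seed(derive_seed(seed, i))
      pl <- .place_restricted(lens, prep$smp, prep$gsmp, retry_cap)
      stats[i] <- .overlap_with_fixed(pl$starts, pl$ends, fc)
      n_unplaceable <- max(n_unplaceable, pl$n_unplaceable)
      n_fallback <- n_fallback + pl$n_fallback
    }
  }
  n_ge <- sum(stats >= observed)
  structure(list(
    observed_overlap_bp = observed,
    inside_density = dens$inside_density,
    outside_density = dens$outside_density,
    oe = dens$oe,
    n_samples = n_samples,
    n_ge = n_ge,
    p_value = (n_ge + 1) / (n_samples + 1),
    p_is_upper_bound = n_ge == 0L,
    p_bound = if (n_ge == 0L) 1 / n_samples else NA_real_,
    seed = seed,
    null_mode = null_mode,
    null_summary = .null_summary(stats),
    n_unplaceable = n_unplaceable,
    n_fallback = n_fallback
  ), class = "enrichment_result")
}

#' @export
print.enrichment_result <- function(x, ...) {
  cat("Monte Carlo overlap enrichment test (", x$null_mode, " null)\n", sep = "")
  cat(sprintf("  observed overlap: %.0f bp\n", x$observed_overlap_bp))
  cat(sprintf("  O/E: %.4g (inside %.4g, outside %.4g per bp)\n",
              x$oe, x$inside_density, x$outside_density))
  if (x$p_is_upper_bound) {
    cat(sprintf("  p < %.3g (0 of %d null samples >= observed; add-one p = %.3g)\n",
                x$p_bound, x$n_samples, x$p_value))
  } else {
    cat(sprintf("  p = %.4g (%d of %d null samples >= observed)\n",
                x$p_value, x$n_ge, x$n_samples))
  }
  cat(sprintf("  null overlap: mean %.1f, sd %.1f bp [seed %s]\n",
              x$null_summary$mean, x$null_summary$sd, format(x$seed)))
  invisible(x)
}

#' Case-control excess enrichment difference (EED) test
#'
#' Compares the enrichment of a peak track inside a *case* region track with
#' its enrichment inside a disjoint *control* region track:
#' `EED = O/E(peaks, case) / O/E(peaks, control)`.  EED above 1 means the
#' peaks preferentially target the case regions beyond what the control
#' regions capture.  Significance comes from the same global permutation null
#' applied to the peak track with both region tracks fixed, using the EED
#' ratio as the statistic.
#'
#' Conventions for degenerate ratios: both O/E zero is an error; a zero
#' control O/E with nonzero case O/E gives `EED = +Inf`, flagged via
#' `is_infinite` and displayed capped at 1e6 (`eed_display`).  Null samples
#' with an undefined ratio (0/0) are counted as exceeding the observed value,
#' which is conservative.
#'
#' @param peaks Peak track whose placement is randomized.
#' @param case,control Disjoint region tracks (as produced by
#'   [split_case_control()]); both fixed under the null.
#' @param n_samples Number of Monte Carlo samples (default 1,000).
#' @param seed Master RNG seed (see [derive_seed()]).
#' @param alternative `"greater"` (default): upper-tail p on the EED ratio;
#'   `"two.sided"`: doubled smaller tail.
#' @param denominator Passed to the O/E computation.
#' @return An object of class `"eed_result"` with `oe_case`, `oe_control`,
#'   `eed`, `eed_display`, `is_infinite`, `n_samples`, `n_ge`, `p_value`,
#'   `seed`, and a null-sample summary of the EED ratio.
#' @export
eed_test <- function(peaks, case, control, n_samples = 1000, seed = 1,
                     alternative = c("greater", "two.sided"),
                     denominator = c("outside", "genome")) {
  alternative <- match.arg(alternative)
  denominator <- match.arg(denominator)
  si <- .check_same_genome(peaks, case)
  .check_same_genome(peaks, control)
  if (coverage_bp(intersect_tracks(case, control)) > 0) {
    .stopf("case and control tracks must be bp-disjoint (use split_case_control())")
  }
  n_samples <- as.integer(n_samples)
  if (is.na(n_samples) || n_samples < 1L) .stopf("n_samples must be >= 1")
  G <- genome_size(si)
  cov_a <- coverage_bp(peaks)
  cov_case <- coverage_bp(case)
  cov_ctrl <- coverage_bp(control)
  if (cov_a == 0) .stopf("peak track is empty")
  if (cov_case == 0 || cov_ctrl == 0) .stopf("case/control track is empty")

  eed_of <- function(ov_case, ov_ctrl) {
    oc <- .oe_from_counts(ov_case, cov_a, cov_case, G, denominator)$oe
    ok <- .oe_from_counts(ov_ctrl, cov_a, cov_ctrl, G, denominator)$oe
    if (oc == 0 && ok == 0) return(NaN)
    if (ok == 0) return(Inf)
    oc / ok
  }
  ov_case_obs <- coverage_bp(intersect_tracks(peaks, case))
  ov_ctrl_obs <- coverage_bp(intersect_tracks(peaks, control))
  oe_case <- .oe_from_counts(ov_case_obs, cov_a, cov_case, G, denominator)$oe
  oe_control <- .oe_from_counts(ov_ctrl_obs, cov_a, cov_ctrl, G, denominator)$oe
  if (oe_case == 0 && oe_control == 0) {
    .stopf("EED undefined: peaks overlap neither case nor control regions")
  }
  eed_obs <- eed_of(ov_case_obs, ov_ctrl_obs)

  fc_case <- .fixed_cov(case, si)
  fc_ctrl <- .fixed_cov(control, si)
  layout <- .track_layout(peaks, si)
  eed_null <- numeric(n_samples)
  for (i in seq_len(n_samples)) {
    set.seed(derive_seed(seed, i))
    segs <- .permute_layout(layout)
    eed_null[i] <- eed_of(.overlap_with_fixed(segs$starts, segs$ends, fc_case),
                          .overlap_with_fixed(segs$starts, segs$ends, fc_ctrl))
  }
  nan <- is.nan(eed_null)
  n_ge <- sum(eed_null[!nan] >= eed_obs) + sum(nan)
  p_ge <- (n_ge + 1) / (n_samples + 1)
  p_value <- if (alternative == "greater") {
    p_ge
  } else {
    n_le <- sum(eed_null[!nan] <= eed_obs) + sum(nan)
    min(1, 2 * min(p_ge, (n_le + 1) / (n_samples + 1)))
  }
  structure(list(
    oe_case = oe_case,
    oe_control = oe_control,
    eed = eed_obs,
    eed_display = min(eed_obs, 1e6),
    is_infinite = is.infinite(eed_obs),
    n_samples = n_samples,
    n_ge = n_ge,
    p_value = p_value,
    alternative = alternative,
    seed = seed,
    null_summary = .null_summary(eed_null[is.finite(eed_null)])
  ), class = "eed_result")
}

#' @export
print.eed_result <- function(x, ...) {
  cat("Case-control excess enrichment difference (EED) test\n")
  cat(sprintf("  O/E case: %.4g   O/E control: %.4g\n", x$oe_case, x$oe_control))
  cat(sprintf("  EED: %.4g%s\n", x$eed_display,
              if (x$is_infinite) " (infinite; control O/E = 0)" else ""))
  cat(sprintf("  p = %.4g (%s, %d null samples, seed %s)\n",
              x$p_value, x$alternative, x$n_samples, format(x$seed)))
  invisible(x)
}
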