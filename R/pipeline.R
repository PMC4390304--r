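#' Run a full co-localization analysis pipeline from a config file
#'
#' Orchestrates the analysis graph on arbitrary inputs: load genome, tracks
#' and SNP sets; build disease-region tracks from SNPs; run overlap
#' enrichment tests (global and/or confounder-restricted nulls), case-control
#' EED tests, peak-centered profiles, and the motif-disruption screen; and
#' return (optionally write) a machine-readable report that, together with
#' the seeds it echoes, fully determines re-execution.
#'
#' The YAML config has the shape:
#' \preformatted{
#' genome: chrom.sizes
#' seed: 1
#' n_samples: 1000
#' tracks: {ebna2: ebna2.bed, vdr: vdr.bed, dhs: dhs.bed}
#' snp_sets: {ms: ms_snps.tsv}
#' region_width: 100000            # or a list for a sensitivity sweep
#' analyses:
#'   - {type: enrichment, a: ebna2, b: "regions:ms"}
#'   - {type: enrichment, a: [ebna2, vdr], b: "regions:ms",
#'      null: restricted, confounder: dhs}
#'   - {type: eed, peaks: ebna2, case: "regions:ms", control: "regions:ra"}
#'   - {type: profile, anchors: ebna2, query: vdr, window: 2000, bin: 25}
#'   - {type: motif_screen, snps: ms, peaks: ebna2, fasta: genome.fa,
#'      motif: motif.meme}
#' }
#' A track reference is a named track, `"regions:<snp set>"` (regions built
#' with `region_width`), or a list of two references whose base-pair
#' intersection forms a derived joint-occupancy track.  Per-analysis
#' `n_samples`, `seed`, `width` override the top-level values.  Each analysis
#' runs under seed `derive_seed(seed, 1000 + index)`; a failing analysis is
#' reported in place and does not abort the others.
#'
#' @param config Path to a YAML file, or an equivalent nested list.
#' @param outdir Optional directory; when given, writes `report.json` and a
#'   `results.tsv` summary table.
#' @return A list of class `"run_report"`: `version`, `config`, `seed`, and
#'   `results` (one entry per analysis with either the result object or an
#'   `error` message).
#' @export
run_pipeline <- function(config, outdir = NULL) {
  cfg <- if (is.character(config)) yaml::read_yaml(config) else config
  for (need in c("genome", "analyses")) {
    if (is.null(cfg[[need]])) .stopf("config lacks required field '%s'", need)
  }
  genome <- if (is.character(cfg$genome)) read_chrom_sizes(cfg$genome)
            else .as_seqinfo(cfg$genome)
  seed <- cfg$seed %||% 1
  n_samples <- cfg$n_samples %||% 1000
  widths <- cfg$region_width %||% 100000

  tracks <- lapply(cfg$tracks %||% list(), function(p) {
    if (is.character(p)) read_bed(p, genome) else as_track(p, genome)
  })
  snp_sets <- lapply(cfg$snp_sets %||% list(), function(p) {
    if (is.character(p)) read_snp_table(p, genome) else snp_set(p, genome)
  })

  # validate all references before any computation
  ref_names <- function(an) {
    unlist(an[names(an) %in% c("a", "b", "peaks", "case", "control",
                               "anchors", "query", "confounder")])
  }
  for (an in cfg$analyses) {
    for (r in ref_names(an)) {
      if (startsWith(r, "regions:")) {
        if (is.null(snp_sets[[sub("^regions:", "", r)]])) {
          .stopf("config names unknown SNP set in '%s'", r)
        }
      } else if (is.null(tracks[[r]])) {
        .stopf("config names unknown track '%s'", r)
      }
    }
  }

  resolve <- function(ref, width) {
    if (is.list(ref) || length(ref) > 1) {
      parts <- lapply(ref, resolve, width = width)
      return(Reduce(intersect_tracks, parts))
    }
    if (startsWith(ref, "regions:")) {
      return(build_regions(snp_sets[[sub("^regions:", "", ref)]], width,
                           genome = genome))
    }
    tracks[[ref]]
  }

  run_one <- function(an, idx) {
    a_seed <- an$seed %||% derive_seed(seed, 1000 + idx)
    ns <- an$n_samples %||% n_samples
    width <- an$width %||% widths[[1]]
    switch(an$type,
      enrichment = {
        null_mode <- an[["null"]] %||% "global"
        mc_enrichment_test(
          resolve(an$a, width), resolve(an$b, width),
          n_samples = ns, null_mode = null_mode,
          confounder = if (null_mode == "restricted" &&
                           !is.null(an$confounder))
            resolve(an$confounder, width),
          seed = a_seed)
      },
      eed = {
        cc <- split_case_control(resolve(an$case, width),
                                 resolve(an$control, width))
        eed_test(resolve(an$peaks, width), cc$case, cc$control,
                 n_samples = ns, seed = a_seed)
      },
      profile = {
        peak_centered_profile(resolve(an$anchors, width),
                              resolve(an$query, width),
                              window_bp = an$window %||% 2000,
                              bin_bp = an$bin %||% 25)
      },
      motif_screen = {
        wins <- build_snp_windows(snp_sets[[an$snps]],
                                  resolve(an$peaks, width),
                                  flank_bp = an$flank %||% 100)
        snp_disruption_screen(wins, an$fasta,
                              read_meme_motif(an$motif),
                              alpha = an$alpha %||% 0.05)
      },
      .stopf("unknown analysis type '%s'", an$type))
  }

  results <- vector("list", length(cfg$analyses))
  for (idx in seq_along(cfg$analyses)) {
    an <- cfg$analyses[[idx]]
    label <- an$label %||% sprintf("analysis_%d (%s)", idx, an$type)
    results[[idx]] <- tryCatch(
      list(label = label, type = an$type,
           seed = an$seed %||% derive_seed(seed, 1000 + idx),
           result = run_one(an, idx)),
      error = function(e) list(label = label, type = an$type,
                               error = conditionMessage(e)))
  }
  names(results) <- vapply(results, `[[`, "", "label")

  report <- structure(list(
    version = as.character(utils::packageVersion("colocperm")),
    seed = seed,
    config = cfg,
    results = results,
    n_errors = sum(vapply(results, function(r) !is.null(r$error), FALSE))
  ), class = "run_report")
  if (!is.null(outdir)) write_run_report(report, outdir)
  report
}

#' Write a pipeline report to disk
#'
#' Emits `report.json` (the full report) and `results.tsv`, a summary table
#' with one row per enrichment/EED analysis (label, O/E, p-value, EED).
#'
#' @param report A `"run_report"` from [run_pipeline()].
#' @param outdir Output directory (created if needed).
#' @return Invisibly, `outdir`.
#' @export
write_run_report <- function(report, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  rows <- lapply(report$results, function(r) {
    if (!is.null(r$error)) {
      return(data.frame(analysis = r$label, type = r$type, oe = NA, p_value = NA,
                        eed = NA, error = r$error))
    }
    x <- r$result
    data.frame(
      analysis = r$label, type = r$type,
      oe = if (inherits(x, "enrichment_result")) x$oe else NA,
      p_value = if (!is.null(x$p_value)) x$p_value else NA,
      eed = if (inherits(x, "eed_result")) x$eed_display else NA,
      error = NA_character_)
  })
  utils::write.table(do.call(rbind, rows), file.path(outdir, "results.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(.report_to_list(report),
                       file.path(outdir, "report.json"),
                       auto_unbox = TRUE, digits = NA, na = "null",
                       pretty = TRUE, force = TRUE)
  invisible(outdir)
}

.report_to_list <- function(report) {
  res <- lapply(report$results, function(r) {
    if (!is.null(r$error)) return(r)
    x <- r$result
    if (inherits(x, c("enrichment_result", "eed_result"))) {
      r$result <- unclass(x)
    } else if (inherits(x, "profile_histogram")) {
      r$result <- unclass(x)
    } else if (is.data.frame(x)) {
      r$result <- x
    } else {
      r$result <- NULL
    }
    r
  })
  list(version = report$version, seed = report$seed, config = report$config,
       n_errors = report$n_errors, results = res)
}

#' @export
print.run_report <- function(x, ...) {
  cat(sprintf("colocperm run report (v%s, seed %s): %d analyses, %d error(s)\n",
              x$version, format(x$seed), length(x$results), x$n_errors))
  for (r in x$results) {
    if (!is.null(r$error)) {
      cat(sprintf("  %-30s ERROR: %s\n", r$label, r$error))
    } else if (inherits(r$result, "enrichment_result")) {
      cat(sprintf("  %-30s O/E %.4g, p %s\n", r$label, r$result$oe,
                  if (r$result$p_is_upper_bound)
                    sprintf("< %.3g", r$result$p_bound)
                  else sprintf("= %.4g", r$result$p_value)))
    } else if (inherits(r$result, "eed_result")) {
      cat(sprintf("  %-30s EED %.4g, p = %.4g\n", r$label,
                  r$result$eed_display, r$result$p_value))
    } else if (inherits(r$result, "profile_histogram")) {
      cat(sprintf("  %-30s profile, %d counts\n", r$label,
                  sum(r$result$counts)))
    } else if (is.data.frame(r$result)) {
      cat(sprintf("  %-30s screen: %d SNPs, %d significant\n", r$label,
                  nrow(r$result), sum(r$result$significant, na.rm = TRUE)))
    }
  }
  invisible(x)
}
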