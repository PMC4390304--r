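#' Configuration for the synthetic-data generator
#'
#' Bundles every knob of the simulator with defaults chosen to emulate a
#' ChIP-seq co-localization study at desk scale: a multi-chromosome genome,
#' disease-associated region tracks, peak tracks with a controllable planted
#' observed-vs-expected enrichment, an open-chromatin-like confounder track
#' that can mediate spurious enrichment, and motif windows with planted
#' disruptive and neutral variants.
#'
#' @param seed Master seed; all outputs are deterministic given it.
#' @param n_chroms,chrom_length_bp Genome shape (default 4 x 25 Mb).
#' @param n_regions,region_width_bp Disease-region track: number and width of
#'   regions (default 500 x 10 kb, i.e. 5% of the genome).
#' @param n_peaks Number of peaks (default 10,000).
#' @param peak_width_mean_bp,peak_width_sd_bp,peak_width_min_bp Peak widths
#'   are drawn from a normal distribution truncated below at
#'   `peak_width_min_bp` (defaults 300/100/20 bp, typical of transcription
#'   factor peak calls).
#' @param target_oe Planted O/E enrichment of peaks inside regions
#'   (default 5); 1 places peaks uniformly.
#' @param confounder_density Fraction of the genome covered by the confounder
#'   track (default 0.02).
#' @param confounder_width_bp Width of each confounder interval (default 600).
#' @param confounder_mediated If `TRUE`, peaks are placed only inside the
#'   confounder track and the confounder is itself enriched inside regions
#'   (`confounder_region_oe`), inducing a spurious peak-region association
#'   with no direct coupling.
#' @param confounder_region_oe Planted O/E of the confounder inside regions
#'   in the mediated scenario (default 8).
#' @param motif_consensus Consensus used for the planted binding motif
#'   (default `"CGTGGGAA"`, the core recognition sequence of an RBPJ-class
#'   factor).
#' @param motif_p_consensus Per-position consensus-base probability of the
#'   planted PWM (default 0.97).
#' @param n_snps Number of SNP windows for the motif screen (default 100).
#' @param fraction_disruptive Fraction of SNPs planted to hit the motif's
#'   highest-information column with the worst-scoring alternate base
#'   (default 0.2).
#' @param fraction_motif Fraction of non-disruptive windows that still carry
#'   an intact motif occurrence away from the SNP (default 0.5).
#' @param flank_bp SNP window flank (default 100, for 201 bp windows).
#' @return A list of class `"sim_config"`.
#' @export
sim_config <- function(seed = 1,
                       n_chroms = 4, chrom_length_bp = 25e6,
                       n_regions = 500, region_width_bp = 10000,
                       n_peaks = 10000,
                       peak_width_mean_bp = 300, peak_width_sd_bp = 100,
                       peak_width_min_bp = 20,
                       target_oe = 5,
                       confounder_density = 0.02, confounder_width_bp = 600,
                       confounder_mediated = FALSE, confounder_region_oe = 8,
                       motif_consensus = "CGTGGGAA", motif_p_consensus = 0.97,
                       n_snps = 100, fraction_disruptive = 0.2,
                       fraction_motif = 0.5, flank_bp = 100) {
  cfg <- as.list(environment())
  if (cfg$target_oe < 0) .stopf("target_oe must be >= 0")
  if (cfg$n_chroms < 1 || cfg$chrom_length_bp < 1) .stopf("invalid genome shape")
  structure(cfg, class = "sim_config")
}

.sim_genome <- function(cfg) {
  Genome(stats::setNames(rep(cfg$chrom_length_bp, cfg$n_chroms),
                         paste0("chr", seq_len(cfg$n_chroms))))
}

# draw one legal start per segment length within the sampler's intervals
.draw_starts <- function(lengths, smp) {
  vapply(lengths, .draw_legal_start, numeric(1), smp = smp)
}

# place segments wholly inside the sampler's intervals without mutual
# overlap: draw all starts, then iteratively redraw colliding segments
.place_set <- function(lengths, smp, max_iter = 200L, what = "segment") {
  n <- length(lengths)
  if (n == 0L) return(list(starts = numeric(0), ends = numeric(0)))
  starts <- .draw_starts(lengths, smp)
  if (anyNA(starts)) {
    .stopf("%d %s(s) fit in no target interval", sum(is.na(starts)), what)
  }
  for (iter in seq_len(max_iter)) {
    o <- order(starts)
    bad_o <- which(starts[o][-1] < (starts + lengths)[o][-n])
    if (length(bad_o) == 0L) {
      return(list(starts = starts, ends = starts + lengths))
    }
    redo <- o[bad_o + 1L]
    starts[redo] <- .draw_starts(lengths[redo], smp)
  }
  .stopf("could not place %ss without overlap after %d rounds (config too dense)",
         what, max_iter)
}

# inside-placement probability q solving the O/E identity
# oe = [q / f] / [(1 - q) / (1 - f)]
.inside_prob <- function(target_oe, f) {
  target_oe * f / (target_oe * f + (1 - f))
}

#' Simulate genome, region, peak and confounder tracks with planted truth
#'
#' Generates a complete synthetic input set for the enrichment pipeline.
#' Peak placement achieves an expected inside/outside density ratio equal to
#' `target_oe`: each peak falls inside the region track with probability
#' `q = oe*f / (oe*f + 1 - f)` (`f` = region coverage fraction) and is placed
#' uniformly among legal starts within the chosen stratum.  In the
#' confounder-mediated scenario peaks are placed only inside the confounder
#' track, which is itself enriched inside regions, so any peak-region
#' association is entirely indirect.
#'
#' @param cfg A [sim_config()].
#' @return A list: `genome`, `regions`, `peaks`, `confounder` (tracks), and
#'   `truth` (planted parameters plus the realized coverage fractions and
#'   inside-placement probability).
#' @export
simulate_tracks <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  si <- .sim_genome(cfg)
  G <- genome_size(si)
  if (cfg$n_peaks * cfg$peak_width_mean_bp > 0.5 * G) {
    .stopf("infeasible config: peaks would cover more than half the genome")
  }
  set.seed(derive_seed(cfg$seed, 0))
  offs <- .chrom_offsets(si)
  lens <- as.double(GenomeInfoDb::seqlengths(si))
  chrom_smp <- .interval_sampler(offs, offs + lens)

  # disease regions: equal-width, mutually non-overlapping
  reg <- .place_set(rep(cfg$region_width_bp, cfg$n_regions), chrom_smp,
                    what = "region")
  regions <- .segments_to_track(reg$starts, reg$ends, si)
  f <- coverage_bp(regions) / G
  reg_smp <- .interval_sampler(reg$starts, reg$ends)
  out_lin <- .complement_linear(reg$starts, reg$ends, offs, lens)
  out_smp <- .interval_sampler(out_lin$starts, out_lin$ends)

  # confounder track
  n_conf <- max(1L, round(cfg$confounder_density * G / cfg$confounder_width_bp))
  if (cfg$confounder_mediated) {
    q_conf <- .inside_prob(cfg$confounder_region_oe, f)
    n_in <- stats::rbinom(1, n_conf, q_conf)
    cin <- .place_set(rep(cfg$confounder_width_bp, n_in), reg_smp,
                      what = "confounder interval")
    cout <- .place_set(rep(cfg$confounder_width_bp, n_conf - n_in), out_smp,
                       what = "confounder interval")
    conf_starts <- c(cin$starts, cout$starts)
    conf_ends <- c(cin$ends, cout$ends)
  } else {
    cg <- .place_set(rep(cfg$confounder_width_bp, n_conf), chrom_smp,
                     what = "confounder interval")
    conf_starts <- cg$starts
    conf_ends <- cg$ends
  }
  confounder <- .segments_to_track(conf_starts, conf_ends, si)

  # peak widths: truncated normal
  pw <- round(stats::rnorm(cfg$n_peaks, cfg$peak_width_mean_bp,
                           cfg$peak_width_sd_bp))
  pw <- pmax(pw, cfg$peak_width_min_bp)
  if (cfg$confounder_mediated) {
    pw <- pmin(pw, cfg$confounder_width_bp)
    conf_smp <- .interval_sampler(conf_starts, conf_ends)
    pk <- .place_set(pw, conf_smp, what = "peak")
    q <- NA_real_
  } else {
    q <- .inside_prob(cfg$target_oe, f)
    inside <- stats::rbinom(cfg$n_peaks, 1, q) == 1
    pin <- .place_set(pw[inside], reg_smp, what = "peak")
    pout <- .place_set(pw[!inside], out_smp, what = "peak")
    pk <- list(starts = c(pin$starts, pout$starts),
               ends = c(pin$ends, pout$ends))
  }
  peaks <- .segments_to_track(pk$starts, pk$ends, si)

  realized <- oe_ratio(peaks, regions)
  list(genome = si, regions = regions, peaks = peaks, confounder = confounder,
       truth = list(seed = cfg$seed,
                    target_oe = cfg$target_oe,
                    confounder_mediated = cfg$confounder_mediated,
                    confounder_region_oe = if (cfg$confounder_mediated)
                      cfg$confounder_region_oe else NA_real_,
                    region_fraction = f,
                    inside_prob = q,
                    n_peaks = cfg$n_peaks,
                    realized_oe = realized$oe))
}

# complement of a set of linear segments within chromosome bounds
.complement_linear <- function(starts, ends, offs, lens) {
  o <- order(starts)
  s <- starts[o]; e <- ends[o]
  gs <- gl_s <- vector("list", length(offs))
  for (k in seq_along(offs)) {
    lo <- offs[k]; hi <- offs[k] + lens[k]
    in_k <- s >= lo & s < hi
    bs <- c(lo, e[in_k]); be <- c(s[in_k], hi)
    keep <- be > bs
    gs[[k]] <- bs[keep]; gl_s[[k]] <- be[keep]
  }
  list(starts = unlist(gs), ends = unlist(gl_s))
}

#' Simulate disjoint case/control region tracks with planted excess
#'
#' Builds two disjoint region tracks and a peak track whose coverage density
#' is `oe_case` (respectively `oe_control`) times the background density
#' inside the case (control) regions, so the planted excess enrichment
#' difference is `oe_case / oe_control`.
#'
#' @param seed Master seed.
#' @param n_chroms,chrom_length_bp Genome shape.
#' @param n_regions_each Regions per track.
#' @param region_width_bp Region width.
#' @param n_peaks Number of peaks.
#' @param peak_width_bp Peak width (fixed).
#' @param oe_case,oe_control Planted density multipliers relative to the
#'   background outside both region tracks.
#' @return A list: `genome`, `case`, `control`, `peaks`, `truth` (with the
#'   planted `eed = oe_case / oe_control`).
#' @export
simulate_case_control_tracks <- function(seed = 1, n_chroms = 2,
                                         chrom_length_bp = 10e6,
                                         n_regions_each = 100,
                                         region_width_bp = 2000,
                                         n_peaks = 5000, peak_width_bp = 200,
                                         oe_case = 5, oe_control = 5) {
  si <- Genome(stats::setNames(rep(chrom_length_bp, n_chroms),
                               paste0("chr", seq_len(n_chroms))))
  G <- genome_size(si)
  set.seed(derive_seed(seed, 0))
  offs <- .chrom_offsets(si)
  lens <- as.double(GenomeInfoDb::seqlengths(si))
  chrom_smp <- .interval_sampler(offs, offs + lens)

  both <- .place_set(rep(region_width_bp, 2 * n_regions_each), chrom_smp,
                     what = "region")
  idx <- sample.int(2 * n_regions_each, n_regions_each)
  cs <- both$starts[idx]; ce <- both$ends[idx]
  ks <- both$starts[-idx]; ke <- both$ends[-idx]
  case <- .segments_to_track(cs, ce, si)
  control <- .segments_to_track(ks, ke, si)

  f_case <- coverage_bp(case) / G
  f_ctrl <- coverage_bp(control) / G
  p <- c(oe_case * f_case, oe_control * f_ctrl, 1 - f_case - f_ctrl)
  p <- p / sum(p)
  stratum <- sample.int(3, n_peaks, replace = TRUE, prob = p)
  out_lin <- .complement_linear(both$starts, both$ends, offs, lens)
  smps <- list(.interval_sampler(cs, ce), .interval_sampler(ks, ke),
               .interval_sampler(out_lin$starts, out_lin$ends))
  parts <- lapply(1:3, function(k) {
    .place_set(rep(peak_width_bp, sum(stratum == k)), smps[[k]], what = "peak")
  })
  peaks <- .segments_to_track(unlist(lapply(parts, `[[`, "starts")),
                              unlist(lapply(parts, `[[`, "ends")), si)
  list(genome = si, case = case, control = control, peaks = peaks,
       truth = list(seed = seed, oe_case = oe_case, oe_control = oe_control,
                    eed = oe_case / oe_control,
                    f_case = f_case, f_control = f_ctrl))
}

#' Simulate SNP windows with planted motif occurrences and variants
#'
#' Generates background-random sequence windows of `2*flank_bp + 1` bp, one
#' per SNP, with the SNP at the center.  Disruptive SNPs sit on the
#' highest-information column of a planted consensus occurrence and carry the
#' worst-scoring alternate base, so their expected best-hit score loss equals
#' the closed-form column log-odds difference.  Neutral SNPs are placed at
#' least one motif width away from any planted occurrence.
#'
#' @param cfg A [sim_config()]; uses `motif_consensus`, `motif_p_consensus`,
#'   `n_snps`, `fraction_disruptive`, `fraction_motif`, `flank_bp`, `seed`.
#' @return A list: `genome` (one pseudo-chromosome per window), `sequences`
#'   (named `DNAStringSet`), `snps` (SNP set), `peaks` (track covering every
#'   window, so all SNPs enter the screen), `pwm` (the planted motif), and
#'   `truth` (per-SNP label, occurrence placement, and the closed-form
#'   `expected_delta` for disruptive SNPs).
#' @export
simulate_motif_sequences <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  w <- nchar(cfg$motif_consensus)
  if (w < 4) .stopf("motif consensus must be at least 4 bp")
  win_len <- 2L * cfg$flank_bp + 1L
  if (win_len < 3L * w) .stopf("windows too short to separate SNPs from motifs")
  set.seed(derive_seed(cfg$seed, 1))
  mot <- pwm_from_consensus(cfg$motif_consensus, cfg$motif_p_consensus)
  center <- cfg$flank_bp                       # 0-based offset of the SNP
  info <- apply(mot$probs * mot$lo_int / 1000, 1, sum)
  icol <- which.max(info)                      # highest-information column
  cons <- strsplit(toupper(cfg$motif_consensus), "")[[1]]
  worst <- .BASES[apply(mot$lo_int, 1, which.min)]

  n_dis <- round(cfg$fraction_disruptive * cfg$n_snps)
  label <- rep("neutral", cfg$n_snps)
  if (n_dis > 0) label[seq_len(n_dis)] <- "disruptive"
  ids <- sprintf("snp_%03d", seq_len(cfg$n_snps))
  win_names <- sprintf("win_%03d", seq_len(cfg$n_snps))

  seqs <- character(cfg$n_snps)
  ref <- alt <- character(cfg$n_snps)
  has_motif <- logical(cfg$n_snps)
  occ_offset <- rep(NA_integer_, cfg$n_snps)
  expected_delta <- rep(NA_real_, cfg$n_snps)

  far_offsets <- setdiff(0:(win_len - w),
                         (center - 2L * w + 1L):(center + w - 1L + w))
  for (i in seq_len(cfg$n_snps)) {
    chars <- sample(.BASES, win_len, replace = TRUE)
    if (label[i] == "disruptive") {
      o <- center - (icol - 1L)                # align column icol with the SNP
      chars[o + seq_len(w)] <- cons
      ref[i] <- cons[icol]
      alt[i] <- worst[icol]
      has_motif[i] <- TRUE
      occ_offset[i] <- o
      expected_delta[i] <- (mot$lo_int[icol, ref[i]] -
                            mot$lo_int[icol, alt[i]]) / 1000
    } else {
      if (stats::runif(1) < cfg$fraction_motif) {
        o <- sample(far_offsets, 1)
        chars[o + seq_len(w)] <- cons
        has_motif[i] <- TRUE
        occ_offset[i] <- o
      }
      ref[i] <- chars[center + 1L]
      alt[i] <- sample(setdiff(.BASES, ref[i]), 1)
    }
    seqs[i] <- paste(chars, collapse = "")
  }

  si <- Genome(stats::setNames(rep(win_len, cfg$n_snps), win_names))
  sequences <- Biostrings::DNAStringSet(stats::setNames(seqs, win_names))
  snps <- snp_set(data.frame(chrom = win_names, pos = center + 1L, id = ids,
                             ref = ref, alt = alt,
                             stringsAsFactors = FALSE), si)
  peaks <- as_track(data.frame(chrom = win_names, start = 0, end = win_len), si)
  truth <- data.frame(id = ids, label = label, has_motif = has_motif,
                      occ_offset = occ_offset,
                      expected_delta = expected_delta,
                      stringsAsFactors = FALSE)
  list(genome = si, sequences = sequences, snps = snps, peaks = peaks,
       pwm = mot, truth = truth)
}

#' Write a simulation bundle to disk
#'
#' Emits the simulated objects in their standard plain-text formats:
#' `chrom.sizes`, one BED file per track, `snps.tsv`, `windows.fasta`, and a
#' `truth.json` sidecar with the planted ground truth, so downstream runs
#' never need to re-derive it.
#'
#' @param sim Output of [simulate_tracks()], [simulate_case_control_tracks()]
#'   or [simulate_motif_sequences()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the vector of files written.
#' @export
write_simulation <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- character(0)
  emit <- function(f) files <<- c(files, f)
  si <- sim$genome
  f <- file.path(dir, "chrom.sizes")
  writeLines(sprintf("%s\t%.0f", GenomeInfoDb::seqnames(si),
                     as.double(GenomeInfoDb::seqlengths(si))), f)
  emit(f)
  for (nm in intersect(names(sim), c("regions", "peaks", "confounder",
                                     "case", "control"))) {
    f <- file.path(dir, paste0(nm, ".bed"))
    write_bed(sim[[nm]], f)
    emit(f)
  }
  if (!is.null(sim$snps)) {
    f <- file.path(dir, "snps.tsv")
    utils::write.table(sim$snps, f, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    emit(f)
  }
  if (!is.null(sim$sequences)) {
    f <- file.path(dir, "windows.fasta")
    Biostrings::writeXStringSet(sim$sequences, f)
    emit(f)
  }
  if (!is.null(sim$truth)) {
    f <- file.path(dir, "truth.json")
    jsonlite::write_json(sim$truth, f, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE, na = "null")
    emit(f)
  }
  invisible(files)
}
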