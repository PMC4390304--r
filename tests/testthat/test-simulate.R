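small_cfg <- function(seed = 1, ...) {
  sim_config(seed = seed, n_chroms = 2, chrom_length_bp = 2e6,
             n_regions = 50, region_width_bp = 2000, n_peaks = 800,
             peak_width_mean_bp = 200, peak_width_sd_bp = 60, ...)
}

test_that("simulated tracks are valid and deterministic", {
  sim <- simulate_tracks(small_cfg(seed = 9))
  for (t in list(sim$regions, sim$peaks, sim$confounder)) {
    expect_identical(normalize_track(t), t)
    expect_gt(coverage_bp(t), 0)
  }
  sim2 <- simulate_tracks(small_cfg(seed = 9))
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  write_simulation(sim, d1)
  write_simulation(sim2, d2)
  for (f in c("chrom.sizes", "regions.bed", "peaks.bed", "confounder.bed")) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)))
  }
  expect_true(file.exists(file.path(d1, "truth.json")))
  tj <- jsonlite::read_json(file.path(d1, "truth.json"))
  expect_equal(tj$target_oe, 5)
  # different seeds give different tracks
  sim3 <- simulate_tracks(small_cfg(seed = 10))
  expect_false(identical(GenomicRanges::start(sim$peaks),
                         GenomicRanges::start(sim3$peaks)))
})

test_that("planted O/E of 1 yields a near-null measured enrichment", {
  sim <- simulate_tracks(sim_config(seed = 31, target_oe = 1))
  expect_gt(sim$truth$realized_oe, 0.9)
  expect_lt(sim$truth$realized_oe, 1.1)
})

test_that("the inside-placement probability solves the O/E identity", {
  f <- 0.05
  for (t in c(1, 2, 5, 10)) {
    q <- colocperm:::.inside_prob(t, f)
    expect_equal((q / f) / ((1 - q) / (1 - f)), t)
  }
  expect_equal(colocperm:::.inside_prob(0, f), 0)
})

test_that("infeasible configurations are rejected", {
  expect_error(simulate_tracks(sim_config(n_chroms = 1, chrom_length_bp = 1e5,
                                          n_peaks = 10000)),
               "infeasible")
})

test_that("mediated scenario couples peaks to regions only via the confounder", {
  sim <- simulate_tracks(sim_config(seed = 41, n_chroms = 2,
                                    chrom_length_bp = 5e6, n_regions = 100,
                                    region_width_bp = 5000, n_peaks = 400,
                                    peak_width_mean_bp = 300,
                                    confounder_density = 0.05,
                                    confounder_mediated = TRUE))
  # all peak bp inside the confounder
  expect_equal(coverage_bp(intersect_tracks(sim$peaks, sim$confounder)),
               coverage_bp(sim$peaks))
  # the spurious association is present
  expect_gt(sim$truth$realized_oe, 2)
})

test_that("motif sequence generator plants what it claims", {
  cfg <- sim_config(seed = 51, n_snps = 30, fraction_disruptive = 0.2,
                    fraction_motif = 0.5)
  ms <- simulate_motif_sequences(cfg)
  expect_length(ms$sequences, 30)
  expect_true(all(Biostrings::width(ms$sequences) == 201))
  tr_ <- ms$truth
  expect_equal(sum(tr_$label == "disruptive"), 6)
  w <- nchar(cfg$motif_consensus)
  # planted occurrences really are the consensus at the recorded offset
  for (i in which(tr_$has_motif)) {
    s <- as.character(Biostrings::subseq(ms$sequences[[i]],
                                         tr_$occ_offset[i] + 1,
                                         tr_$occ_offset[i] + w))
    expect_equal(s, cfg$motif_consensus)
  }
  # neutral occurrences stay at least one motif width from the SNP
  neu <- tr_$has_motif & tr_$label == "neutral"
  expect_true(all(abs(tr_$occ_offset[neu] + (w - 1) / 2 - 100) >= w))
  # determinism
  ms2 <- simulate_motif_sequences(cfg)
  expect_identical(as.character(ms$sequences), as.character(ms2$sequences))
})

test_that("without planted motifs most screen deltas are exactly zero", {
  cfg <- sim_config(seed = 61, n_snps = 60, fraction_disruptive = 0,
                    fraction_motif = 0)
  ms <- simulate_motif_sequences(cfg)
  scr <- snp_disruption_screen(build_snp_windows(ms$snps, ms$peaks),
                               ms$sequences, ms$pwm)
  # a SNP only shifts the best hit when that hit's window spans it, so the
  # bulk of background windows give delta identical to zero
  expect_gt(mean(scr$delta == 0), 0.6)
  expect_equal(median(scr$delta), 0)
})

test_that("case/control generator plants the requested excess", {
  cc <- simulate_case_control_tracks(seed = 71, n_peaks = 4000,
                                     oe_case = 10, oe_control = 5)
  expect_length(intersect_tracks(cc$case, cc$control), 0)
  expect_equal(cc$truth$eed, 2)
  r_case <- oe_ratio(cc$peaks, cc$case)$oe
  r_ctrl <- oe_ratio(cc$peaks, cc$control)$oe
  expect_gt(r_case / r_ctrl, 1.5)
  expect_lt(r_case / r_ctrl, 2.5)
})
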