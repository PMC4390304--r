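test_that("O/E ratio matches bp counting and handles edge cases", {
  g <- Genome(c(chr1 = 1000))
  b <- tr(g, "chr1", 0, 200)
  a <- tr(g, "chr1", c(50, 600), c(150, 700))
  r <- oe_ratio(a, b)
  expect_equal(r$inside_density, 0.5)
  expect_equal(r$outside_density, 0.125)
  expect_equal(r$oe, 4)

  # uniform coverage: a = whole genome minus nothing
  whole <- tr(g, "chr1", 0, 1000)
  expect_equal(oe_ratio(whole, b)$oe, 1)
  # no overlap
  expect_equal(oe_ratio(tr(g, "chr1", 500, 600), b)$oe, 0)
  # a entirely inside b
  expect_equal(oe_ratio(tr(g, "chr1", 10, 20), b)$oe, Inf)

  expect_error(oe_ratio(GenomicRanges::GRanges(seqinfo = g), b), "'a' is empty")
  expect_error(oe_ratio(a, GenomicRanges::GRanges(seqinfo = g)), "'b' is empty")
  expect_error(oe_ratio(a, whole), "whole genome")

  # genome-density denominator: inside_density / (|a| / G)
  rg <- oe_ratio(a, b, denominator = "genome")
  expect_equal(rg$oe, 0.5 / (200 / 1000))
})

test_that("O/E agrees with the per-bp oracle on random pairs", {
  g <- toy_genome()
  G <- genome_size(g)
  for (seed in 1:25) {
    a <- random_track(g, 30, max_len = 80, seed = seed)
    b <- random_track(g, 10, max_len = 400, seed = seed + 777)
    va <- bp_vector(a, g); vb <- bp_vector(b, g)
    inside <- sum(va & vb) / sum(vb)
    outside <- sum(va & !vb) / (G - sum(vb))
    r <- oe_ratio(a, b)
    expect_equal(r$inside_density, inside)
    expect_equal(r$outside_density, outside)
    if (outside > 0) expect_equal(r$oe, inside / outside)
  }
})

test_that("adding a-coverage inside b never decreases the O/E", {
  g <- Genome(c(chr1 = 100000))
  b <- tr(g, "chr1", 10000, 30000)
  a <- tr(g, "chr1", c(500, 40000), c(900, 40500))
  prev <- oe_ratio(a, b)$oe
  for (k in 1:8) {
    extra_start <- 10000 + k * 2000
    a <- normalize_track(c(a, tr(g, "chr1", extra_start, extra_start + 300)))
    cur <- oe_ratio(a, b)$oe
    expect_gte(cur, prev)
    prev <- cur
  }
})

test_that("empirical p-values follow the add-one convention", {
  g <- toy_genome()
  b <- random_track(g, 10, max_len = 300, seed = 1)
  a <- random_track(g, 20, max_len = 60, seed = 2)
  res <- mc_enrichment_test(a, b, n_samples = 50, seed = 5)
  expect_equal(res$p_value, (res$n_ge + 1) / (res$n_samples + 1))
  expect_identical(res$p_is_upper_bound, res$n_ge == 0L)

  # observed statistic of zero is never exceeded strictly: p = 1
  far_a <- tr(g, "chrB", 3900, 3950)
  far_b <- tr(g, "chrB", 0, 50)
  # choose b so that some null samples overlap; observed overlap possible = 0
  res0 <- mc_enrichment_test(far_a, far_b, n_samples = 99, seed = 3)
  expect_equal(res0$observed_overlap_bp, 0)
  expect_equal(res0$n_ge, 99L)
  expect_equal(res0$p_value, 1)
})

test_that("restricted-null test requires and uses a confounder", {
  g <- toy_genome()
  a <- random_track(g, 10, max_len = 40, seed = 11)
  b <- random_track(g, 5, max_len = 300, seed = 12)
  expect_error(mc_enrichment_test(a, b, 10, null_mode = "restricted"),
               "confounder")
  conf <- tr(g, c("chrA", "chrB"), c(0, 0), c(3000, 2000))
  res <- mc_enrichment_test(a, b, n_samples = 30, null_mode = "restricted",
                            confounder = conf, seed = 4)
  expect_s3_class(res, "enrichment_result")
  expect_equal(res$null_mode, "restricted")
})

test_that("EED follows its ratio definition and degenerate conventions", {
  g <- Genome(c(chr1 = 100000, chr2 = 100000))
  case <- tr(g, "chr1", 10000, 20000)
  ctrl <- tr(g, "chr2", 10000, 20000)
  peaks <- tr(g, c("chr1", "chr2", "chr1"),
              c(12000, 12000, 60000), c(12500, 12500, 60500))
  res <- eed_test(peaks, case, ctrl, n_samples = 49, seed = 1)
  oc <- oe_ratio(peaks, case)$oe
  ok <- oe_ratio(peaks, ctrl)$oe
  expect_equal(res$eed, oc / ok)
  expect_equal(res$p_value, (res$n_ge + 1) / (res$n_samples + 1))

  # peaks overlapping case only: infinite EED, capped display
  peaks2 <- tr(g, "chr1", c(12000, 60000), c(12500, 60500))
  res2 <- eed_test(peaks2, case, ctrl, n_samples = 19, seed = 2)
  expect_true(res2$is_infinite)
  expect_equal(res2$eed_display, 1e6)

  # overlapping case/control rejected; no-overlap-at-all rejected
  expect_error(eed_test(peaks, case, tr(g, "chr1", 15000, 30000), 10),
               "disjoint")
  peaks3 <- tr(g, "chr1", 60000, 60500)
  expect_error(eed_test(peaks3, case, ctrl, 10), "neither")
})
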