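test_that("BED reading parses, merges and validates", {
  g <- Genome(c(chr1 = 1000))
  f <- withr::local_tempfile()

  writeLines("chr1\t100\t200", f)
  t1 <- read_bed(f, g)
  expect_equal(GenomicRanges::start(t1), 101)
  expect_equal(GenomicRanges::end(t1), 200)

  writeLines(character(0), f)
  expect_length(read_bed(f, g), 0)

  writeLines(c("chr1\t50\t150", "chr1\t100\t250"), f)
  merged <- read_bed(f, g, normalize = TRUE)
  expect_length(merged, 1)
  expect_equal(coverage_bp(merged), 200)

  # header-ish lines skipped, extra columns ignored
  writeLines(c("track name=x", "# comment", "chr1\t0\t10\tpeak1\t960\t+"), f)
  expect_equal(coverage_bp(read_bed(f, g)), 10)

  # malformed lines error with their line number
  writeLines(c("chr1\t0\t10", "chr1\tten\t20"), f)
  expect_error(read_bed(f, g), "line 2.*non-integer")
  writeLines("chr1\t20\t10", f)
  expect_error(read_bed(f, g), "start < end")
  writeLines("chr1\t10", f)
  expect_error(read_bed(f, g), "fewer than 3")

  # unknown chromosomes: strict errors, lenient skips
  writeLines(c("chr1\t0\t10", "chrX\t0\t10"), f)
  expect_error(read_bed(f, g, strict = TRUE), "chrX")
  expect_warning(lenient <- read_bed(f, g, strict = FALSE), "skipped 1")
  expect_equal(coverage_bp(lenient), 10)

  # out-of-bounds intervals are clipped with a warning
  writeLines("chr1\t900\t1200", f)
  expect_warning(clipped <- read_bed(f, g), "clipped")
  expect_equal(coverage_bp(clipped), 100)
})

test_that("BED writing round-trips tracks exactly", {
  g <- toy_genome()
  f <- withr::local_tempfile()

  t0 <- tr(g, "chrA", 0, 10)
  write_bed(t0, f)
  expect_equal(readLines(f), "chrA\t0\t10")
  write_bed(GenomicRanges::GRanges(seqinfo = g), f)
  expect_equal(readLines(f), character(0))

  for (seed in 1:20) {
    t1 <- random_track(g, 30, max_len = 80, seed = seed)
    write_bed(t1, f)
    t2 <- read_bed(f, g)
    expect_true(all(t1 == t2))
    expect_equal(coverage_bp(t1), coverage_bp(t2))
  }
})

test_that("normalization merges adjacency and is idempotent", {
  g <- toy_genome()
  t1 <- tr(g, c("chrA", "chrA"), c(0, 10), c(10, 20))
  expect_length(t1, 1)
  expect_equal(coverage_bp(t1), 20)
  for (seed in 1:10) {
    t2 <- random_track(g, 50, seed = seed)
    expect_identical(normalize_track(t2), t2)
  }
})

test_that("intersect and subtract follow the examples and check genomes", {
  g <- toy_genome()
  a <- tr(g, "chrA", 0, 100)
  b <- tr(g, "chrA", 50, 150)
  ab <- intersect_tracks(a, b)
  expect_equal(as.double(GenomicRanges::start(ab)) - 1, 50)
  expect_equal(as.double(GenomicRanges::end(ab)), 100)
  expect_equal(coverage_bp(subtract_tracks(a, b)), 50)
  expect_length(subtract_tracks(a, a), 0)
  expect_length(intersect_tracks(a, tr(g, "chrB", 0, 100)), 0)

  g2 <- Genome(c(chrA = 6000, chrB = 5000))
  expect_error(intersect_tracks(a, tr(g2, "chrA", 0, 10)), "different genomes")
})

test_that("interval algebra matches the per-bp oracle on random pairs", {
  g <- toy_genome()
  for (seed in 1:40) {
    a <- random_track(g, 25, max_len = 60, seed = seed)
    b <- random_track(g, 25, max_len = 60, seed = seed + 5000)
    va <- bp_vector(a, g); vb <- bp_vector(b, g)
    expect_identical(bp_vector(intersect_tracks(a, b), g), va & vb)
    expect_identical(bp_vector(subtract_tracks(a, b), g), va & !vb)
    # partition law in bp
    expect_equal(coverage_bp(intersect_tracks(a, b)) +
                   coverage_bp(subtract_tracks(a, b)), coverage_bp(a))
  }
})

test_that("overlap_fraction counts joint occupancy at bp level", {
  g <- toy_genome()
  a <- tr(g, c("chrA", "chrA"), c(0, 200), c(100, 300))
  b <- tr(g, "chrA", 50, 250)
  expect_equal(overlap_fraction(a, b), 0.5)
  expect_equal(overlap_fraction(a, tr(g, "chrA", 0, 400)), 1)
  expect_equal(overlap_fraction(a, tr(g, "chrB", 0, 400)), 0)
  expect_error(overlap_fraction(GenomicRanges::GRanges(seqinfo = g), b), "empty")
})

test_that("genome constructors validate their input", {
  expect_error(Genome(c(1000, 2000)), "named")
  expect_error(Genome(c(chr1 = 1000, chr1 = 500)), "duplicated")
  expect_error(Genome(c(chr1 = -5)), "positive")
  f <- withr::local_tempfile()
  writeLines(c("chr1\t1000", "chr2\t500"), f)
  g <- read_chrom_sizes(f)
  expect_equal(genome_size(g), 1500)
  writeLines("chr1\tabc", f)
  expect_error(read_chrom_sizes(f), "non-numeric")
})
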