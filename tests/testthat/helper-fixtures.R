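# Shared fixtures and independent oracles.
#
# The per-base-pair oracle represents a track as a logical occupancy vector
# over the linearized genome; interval algebra then reduces to elementwise
# boolean operations.  It is deliberately naive and independent of the
# package's interval code paths.

bp_vector <- function(track, genome) {
  G <- genome_size(genome)
  offs <- cumsum(c(0, as.double(GenomeInfoDb::seqlengths(genome))))
  v <- logical(G)
  if (length(track)) {
    k <- as.integer(GenomicRanges::seqnames(track))
    s <- as.double(GenomicRanges::start(track)) - 1 + offs[k]
    e <- as.double(GenomicRanges::end(track)) + offs[k]
    for (i in seq_along(s)) v[(s[i] + 1):e[i]] <- TRUE
  }
  v
}

# random normalized track: n intervals of length 1..max_len at uniform starts
random_track <- function(genome, n, max_len = 50, seed = 1) {
  set.seed(seed)
  nm <- GenomeInfoDb::seqnames(genome)
  lens <- as.double(GenomeInfoDb::seqlengths(genome))
  chrom <- sample(nm, n, replace = TRUE, prob = lens)
  L <- sample.int(max_len, n, replace = TRUE)
  s <- floor(runif(n) * (lens[match(chrom, nm)] - L))
  as_track(data.frame(chrom = chrom, start = s, end = s + L), genome)
}

# simple data.frame -> track shorthand
tr <- function(genome, chrom, start, end) {
  as_track(data.frame(chrom = chrom, start = start, end = end), genome)
}

toy_genome <- function() Genome(c(chrA = 6000, chrB = 4000))

# brute-force best PWM hit: enumerate every window on both strands and score
# with plain log2 odds (independent of the package's integer-score scanner)
brute_best_hit <- function(seq, probs, background = rep(0.25, 4),
                           pseudocount = 1e-4) {
  bases <- c("A", "C", "G", "T")
  p <- sweep(probs + pseudocount, 1, rowSums(probs + pseudocount), "/")
  lo <- log2(sweep(p, 2, background, "/"))
  rc <- function(s) chartr("ACGT", "TGCA", paste(rev(strsplit(s, "")[[1]]),
                                                 collapse = ""))
  w <- nrow(probs)
  chars <- strsplit(toupper(seq), "")[[1]]
  best <- list(score = -Inf)
  for (o in 0:(length(chars) - w)) {
    win <- paste(chars[o + seq_len(w)], collapse = "")
    for (st in c("+", "-")) {
      s2 <- if (st == "+") win else rc(win)
      b <- match(strsplit(s2, "")[[1]], bases)
      if (anyNA(b)) next
      sc <- sum(lo[cbind(seq_len(w), b)])
      if (sc > best$score) best <- list(score = sc, offset = o, strand = st)
    }
  }
  best
}
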