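---
title: "Methods: permutation-based co-localization analysis of genomic tracks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: permutation-based co-localization analysis of genomic tracks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(colocperm)
```

# The question and the model

Regulatory-genomics studies repeatedly ask whether one interval track
(transcription-factor peaks, open-chromatin regions, ...) co-localizes with
another (windows around disease-associated SNPs, another factor's peaks)
beyond chance.  `colocperm` formalizes this as an observed-vs-expected
coverage-density ratio with a Monte Carlo permutation null.

## Tracks and coordinates

A *track* is a set of intervals on a fixed genome, held as an unstranded
`GRanges` in normalized form: sorted, with overlapping or book-ended
intervals merged, so consecutive intervals are separated by at least 1 bp.
All statistics are strand-agnostic base-pair occupancy measures, which is
why merging book-ended intervals is harmless: it changes segment counts but
never coverage.  File I/O follows the BED convention (0-based, half-open);
SNP tables are 1-based, the convention of GWAS catalogs, and are converted
exactly once, on interval construction.  One representational limit is
inherited from `GRanges`: individual chromosomes must be shorter than
2^31 − 1 bp (total genome size is accumulated in doubles and may exceed it).

## The O/E statistic

For query track $A$, target track $B$ and genome size $G$:

$$\mathrm{O/E} \;=\; \frac{|A\cap B| \,/\, |B|}
                        {(|A|-|A\cap B|)\,/\,(G-|B|)}$$

the ratio of $A$'s coverage density inside $B$'s segments to its density
outside them.  The statistic is undefined (an error) when $A$ is empty or
when $B$ is empty or covers the whole genome; it is $+\infty$ when $A$ lies
entirely inside $B$.  The phrase "inside vs outside" admits a second
reading — inside density over *marginal* density $|A|/G$ — which is exposed
as `denominator = "genome"`; both denominators are validated against a
per-base-pair counting oracle in the test suite.  The outside-density form
is the default because it is the stricter contrast (the two coincide as
$|B|/G \to 0$).

## The global permutation null

Significance is assessed against randomized placements of $A$ with $B$ held
fixed.  On each chromosome the null preserves **exactly** the multiset of
segment lengths and the multiset of gap lengths — including the two flanking
gaps to the chromosome ends, so $n$ segments contribute $n+1$ gaps.  A draw
permutes the segment order and the gap order independently and lays them out
alternately from the chromosome start (gap, segment, gap, ...).  Segments
never move between chromosomes, because the gap multiset is only meaningful
within one.  The layout starts with a gap; a segment can start at coordinate
0 only when a zero-length flanking gap is permuted into first position, and
the output is deliberately not re-normalized so that such draws remain valid
samples (book-ended segments can occur; coverage statistics are unaffected).

The test statistic is the observed overlap $|A\cap B|$ in base pairs.  Since
every null draw preserves $|A|$, $|B|$ and $G$, the overlap is a monotone
transform of O/E and ranks samples identically.

Empirical p-values use the add-one convention
$p = (n_{\ge} + 1)/(n + 1)$, where $n_{\ge}$ counts null samples with
statistic at or above the observed value.  With $n = 1000$ and no
exceedance this gives $p = 1/1001 = 9.99\times 10^{-4}$, and with
$n = 50{,}000$ the result is reported as the resolution bound
$p < 1/50{,}000 = 2\times10^{-5}$ (`p_is_upper_bound`, `p_bound`).  Ties
count toward $n_{\ge}$, which is conservative.

All Monte Carlo machinery derives the seed of sample $i$ as
`derive_seed(master, i)`, a fixed integer hash; sample $i$ of
`mc_enrichment_test()` is bit-identical to
`permute_track_global(a, derive_seed(master, i))`, which the tests assert.

## The confounder-restricted null

Transcription factors bind predominantly in open chromatin, so a naive test
can mistake shared accessibility for direct association.  The restricted
null conditions on a confounder track: each segment of $A$ is re-placed
uniformly at random among all start positions at which it lies entirely
within some confounder interval.  This is one concrete realization of
"randomize within the confounder"; intensity-weighted alternatives exist but
are not implemented.  Details that make the output a valid track:

* placement is genome-wide across confounder intervals (confinement to a
  third track makes per-chromosome gap preservation impossible anyway);
* segments are placed longest-first; a collision with an already placed
  segment triggers rejection-resampling, capped at `retry_cap` (default
  1000) attempts, then a genome-wide fallback with a warning;
* segments that fit in **no** confounder interval are placed uniformly
  genome-wide and counted in the `n_unplaceable` diagnostic.

Because of collision handling the joint distribution of placements is
approximate (segments are not exactly exchangeable), but the segment-length
multiset is always preserved and, at the densities used here, fallbacks are
rare (the diagnostics expose them when they are not).

## Case-control excess (EED)

To ask whether peaks prefer one region set over another, the two tracks
first mutually discard shared base pairs (`split_case_control()`), which is
the stricter, base-pair-resolution reading of "discarding overlapping
segments"; dropping whole touching segments is available via
`whole_segment = TRUE`.  Then

$$\mathrm{EED} = \frac{\mathrm{O/E}(\text{peaks}, \text{case})}
                     {\mathrm{O/E}(\text{peaks}, \text{control})}$$

with the p-value from the same global null applied to the peak track, using
the EED ratio as the statistic and both region tracks fixed.  Conventions:
$0/0$ is an error for the observed value; $x/0$ is $+\infty$, flagged and
displayed capped at $10^6$; null samples with an undefined ratio count as
exceedances (conservative).  The default tail is upper (`"greater"`),
matching the directional question "is the case excess larger than chance";
a doubled-smaller-tail `"two.sided"` option is provided for symmetric use.

# Profiles

`peak_centered_profile()` bins signed offsets between query-interval
midpoints and anchor-interval midpoints, with midpoints computed by integer
floor division on 0-based half-open coordinates and half-open bins
$[lo, lo+\mathrm{bin})$ spanning $[-\mathrm{window}, +\mathrm{window})$.
Defaults (window 2000 bp, bin 25 bp) are plain display choices, not
statistical ones.  One subtlety: offset 0 is the shared edge of the two
central bins, so for symmetric co-binding noise the histogram maximum is
equally likely to be either of them; "central peak" therefore means the
maximum bin's *closed* interval contains 0.  The package reports raw counts
(each query midpoint contributes once per anchor window it falls in); no
normalization is applied.

# The motif-disruption screen

SNP windows are the SNP position enlarged by 100 bp on each side (201 bp
including the SNP base), retained when they share at least 1 bp with a peak
(half-open intersection, so a SNP exactly 100 bp from a peak edge is still
included).  Scanning uses log2-odds scores against a background base
distribution, discretized to $10^{-3}$ bits; the same integer score lattice
drives both the scan and the dynamic-programming score distribution, so the
per-w-mer p-value — the probability that a single random w-mer scores at
least as high — is exact under the discretization (absolute score error at
most $5\times10^{-4}$ bits per column).  Windows containing `N` score
$-\infty$.  A pseudocount (default $10^{-4}$) keeps log-odds finite.

The *screen* compares the best hit of the window with the reference allele
substituted against the best hit with the alternate allele;
`delta = ref_score − alt_score`.  Because the best hit is a maximum over
roughly 390 scanned windows, its raw w-mer p-value concentrates near
1/390 under the null, and pooling raw values into Benjamini-Hochberg would
flag essentially every window.  Each best-hit p-value is therefore
calibrated to the sequence level with the Šidák correction
$1-(1-p)^{\#\text{windows}}$ — the standard scan-level calibration, slightly
conservative under the positive dependence of overlapping windows — and
q-values are computed jointly across all ref and alt hits (pooled rather
than per-allele; the two choices differ only through the BH denominator and
pooling is the more symmetric one).  A SNP is flagged at $q < 0.05$ for
either allele.  Note the flag marks *significant motif presence* for an
allele; disruption per se is read from `delta`.

# The synthetic-data generator

The generator stands in for the real inputs of a co-localization study —
peak calls, open-chromatin tracks, GWAS SNP lists — with controlled ground
truth, and its defaults define the study conditions used throughout the
tests:

* genome: 4 chromosomes of 25 Mb (large enough for thousands of
  non-colliding peaks, small enough for second-scale tests);
* regions: 500 non-overlapping 10 kb intervals, i.e. a 5% coverage
  fraction, comparable to a genome tiled by widely spaced GWAS windows;
* peaks: 10,000, widths from a normal distribution (mean 300 bp, sd 100 bp)
  truncated below at 20 bp — typical transcription-factor peak-call widths;
* planted enrichment: a peak falls inside the region track with probability
  $q = t f / (t f + 1 - f)$, which makes the *expected* inside/outside
  density ratio equal the target $t$ exactly; placement is uniform among
  the start positions wholly inside the chosen stratum;
* confounder: 600 bp intervals covering 2% of the genome (DHS-like); in the
  *mediated* scenario the confounder is enriched in regions (O/E 8 by
  default) and peaks are placed only inside the confounder, so any
  peak-region association is purely indirect — the scenario the restricted
  null is designed to defuse;
* motif windows: 201 bp of i.i.d. uniform background; disruptive SNPs sit
  on the most informative column of a planted consensus occurrence
  (default `CGTGGGAA`, an RBPJ-class core, at per-position consensus
  probability 0.97) with the worst-scoring alternate base, so their
  expected score loss has a closed form; neutral SNPs stay at least one
  motif width away from any planted occurrence.

What the generator does **not** emulate: chromatin-driven clustering of
peaks, width/GC covariation, LD structure among SNPs, sequencing noise, or
realistic motif degeneracy.  Passing tests therefore demonstrate
correctness and calibration of the *statistics* under their stated null and
alternative models — not robustness to every property of real ChIP-seq
data.

# Numerical and design choices

* **Add-one p-values** — chosen so that a zero-exceedance run at $n=1000$
  prints $9.99\times10^{-4}$ and the $n$-sample resolution bound
  $1/n$ is reported alongside; both conventions are pinned by tests.
* **Score discretization** $10^{-3}$ bits — keeps the DP lattice a few tens
  of thousands of cells wide while bounding score error far below the
  reported 3 decimals.
* **Tie-breaks** — the scan returns the first maximum (forward strand,
  lowest offset); permutation layout has no tie-breaking beyond the drawn
  permutation itself.
* **Degenerate inputs** — empty tracks, whole-genome targets, SNPs without
  alleles, windows shorter than the motif, segments that fit no confounder
  interval: each has a defined error or flagged-fallback path exercised in
  the tests.
* **Region building** — "a region of width $W$ centered on a SNP" is
  realized as $\pm W/2$ around the 0-based position; overlapping per-SNP
  regions are merged (double-counting would inflate bp coverage);
  boundary-crossing regions are clipped with a warning.  MHC-style
  exclusions are left to the caller as ordinary track subtraction rather
  than hard-coded coordinates.
* **Test problem sizes** — the acceptance suite uses 10 kb toy genomes for
  the 1,000-pair per-bp oracle, 99-sample tests for the 200-dataset type-I
  calibration (at $n=99$, $P(p \le 0.05) = 0.05$ exactly under
  exchangeability), 10,000-peak tracks for O/E recovery, 50 replicates for
  confounder rescue, and 20 seeded replicates for the screen-null and
  profile-shape checks.  These sizes were chosen once, from power
  considerations, and are stated here so the suite's sensitivity is
  interpretable.

# Known limitations

* The restricted null's collision handling makes segment placements weakly
  dependent; with dense query tracks and sparse confounders the fallback
  warnings should be heeded.
* Exact p-values for the scan assume an i.i.d. background; real genomic
  background (CpG depletion, repeats) is not modeled.
* No multiple-testing correction is applied across *track pairs* — the
  package tests single pairs, and a user scanning many factors should
  correct downstream.
* Analytical (non-Monte-Carlo) p-values are out of scope; at 50,000 samples
  the resolution floor is $2\times10^{-5}$.
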