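---
title: "Methods: promoter-occupancy statistics in promocc"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: promoter-occupancy statistics in promocc}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(promocc)
```

`promocc` implements the statistics of a promoter-occupancy study: where
a transcription factor's ChIP peaks fall relative to gene models and
empirically mapped TSSs, which sequence motifs explain the binding, how
core-promoter elements are arranged around the dominant TSS, and whether
bound genes respond transcriptionally. This vignette is the package's
account of the underlying models, the tunable parameters, the numerical
conventions, and the limits of what the test suite demonstrates.

## Coordinate conventions

All internal coordinates are 0-based half-open, the BED convention; GTF
input is converted at the boundary (`start - 1`, `end`) and restored on
write. The TSS of a minus-strand transcript is `end - 1`, the biological
5' base of the span. Chromosome names are matched as exact strings: no
"chr" aliasing, because silent namespace merging hides data errors.
bedGraph stands in for bigWig throughout — at the problem sizes this
package targets, text tracks are sufficient and keep the whole pipeline
inspectable.

## Interval association

**Jaccard.** Both sets are merged first (overlapping *and* bookended
intervals coalesce — base-pair set semantics), then
`J = intersection bp / union bp`. The companion count of query intervals
overlapping the other set expresses replicate agreement the way it is
usually quoted ("x% of peaks were also found in ...").

**Relative distance.** Each query is reduced to its midpoint
`floor((start + end)/2)`; for a midpoint `q` between consecutive
reference points `b_prev ≤ q ≤ b_next`, the statistic is
`min(q − b_prev, b_next − q) / (b_next − b_prev)`. Under spatial
independence it is uniform on [0, 0.5]; enrichment near a feature class
skews it toward 0. Queries outside the outermost references have no
defined flanking pair and are dropped and counted (`n_dropped`) rather
than clamped. The default histogram bin width is 0.02, fine enough to
see a flat null. One numerical caveat worth knowing: on integer
coordinates the boundary values 0 and 0.5 each carry half the
probability mass of interior lattice values, so with mean reference
spacing `g` the first and last histogram bins deviate from flatness by
roughly `1/(2g)` even under a perfect null. The test suite therefore
evaluates flatness with references at a mean spacing of 1000 bp, where
the artifact is an order of magnitude below the sampling noise.

**Classification.** A peak is `TSS` if its interval contains any
transcript's TSS coordinate, else `gene_body` if it overlaps any
transcript span, else `intergenic`; every peak is also assigned its
nearest TSS gene with a signed distance (ties broken by lexicographic
gene id, so results are order-independent). Percentages are reported as
integers with round-half-away-from-zero.

**Overlap Fisher test.** There is no canonical 2×2 for "do these interval
sets overlap more than chance": the fourth cell (regions bound by
neither) is not observable. The package uses a genome-slot heuristic:
`n11` = merged `a` intervals overlapping merged `b`, `n12`/`n21` the
non-overlapping counts, and `n22 = floor(G / slot_width) − n11 − n12 −
n21` with `slot_width = mean_width(a) + mean_width(b)`. The slot width is
the combined footprint within which two independently placed intervals
collide; with this choice the sample odds ratio is calibrated to ≈ 1 for
spatially independent sets (median 0.98 over 100 simulated null
replicates in the test suite), whereas normalizing by the single-set
mean width inflates the null OR to ≈ 2. The resulting OR should still be
read as a descriptive enrichment score, not an exact probability
statement.

**Fisher's exact test.** The headline `odds_ratio` is the *sample* odds
ratio `(n11·n22)/(n12·n21)` — the number obtained by dividing published
counts — reported as `+Inf` when only the denominator is zero. The
conditional maximum-likelihood estimate from `stats::fisher.test()` is
exposed alongside (`conditional_mle`); on the reconstructable published
tables the two agree to two decimals. Two-sided p-values are exact
(hypergeometric, fixed margins) and are verified against exhaustive
enumeration for all tables with total ≤ 30.

## Motif scanning

Motifs are published as IUPAC consensus strings, so degenerate-class
matching is the default scanning mode: position `i` matches when every
sequence base lies in the aligned consensus class, with `N` in the
*sequence* matching nothing (assembly gaps never produce hits).
Minus-strand hits come from scanning the reverse-complemented consensus
and are reported in forward coordinates. Overlapping hits are all kept —
downstream semantics are presence/absence per peak, and pruning would
change mask-and-rescan accounting.

PWM mode serves the positional-element scans. The score is the log2
likelihood ratio against a zero-order background (uniform by default,
configurable to genome composition; tools in the FIMO family default to
a sequence-derived background, a documented divergence). The p-value
threshold is exact: the null score distribution is built by
position-wise convolution on an integer grid with step 1/1000 of the
finite score range, and the threshold is the smallest grid score whose
upper tail is ≤ α. Zero-probability cells score `−Inf`; their words are
excluded from the finite grid and the retained mass plus the excluded
mass sums to one (tested to 1e−9). When α is below the probability of
the single best word the threshold is unattainable and the best-word
score is returned with a warning — this is exactly why a 4-bp
exact-match motif cannot pass α = 0.003 (best p = 4⁻⁴ ≈ 0.0039) while a
5-bp one can (4⁻⁵ ≈ 0.00098). The defaults follow the study's scanning
thresholds: α = 0.003 for general promoter elements and α = 0.0002 for
the factor's own motifs.

The mask-and-rescan procedure reports, for an ordered catalog, the
fraction of *remaining* peaks containing each motif, removing the
carriers before moving on — mirroring how iterative de novo discovery
rounds are summarized. The fractions are reproducible by pure set
arithmetic on the presence matrix, which the tests exploit as an oracle.

## CAGE TSS calling

CTSS tables aggregate 5'-tag counts per (chromosome, position, strand);
`tpm = count / total × 1e6` (simple TPM — the power-law normalization
option of CAGE toolkits is out of scope since the study used the simple
scheme). Clustering first discards CTSS below 1 TPM, then:

- **distclu** (default): same-strand positions within `max_dist = 20` bp
  merge transitively. The defaults follow the study's printed clustering
  call, which names the paraclu method *and* a `maxDist` that belongs to
  distance clustering; since the one concrete parameter printed is
  `maxDist = 20`, distance clustering with that gap is the default and
  paraclu is available explicitly.
- **paraclu**: recursive maximal-density segmentation. A segment's
  `max_density` is total weight over its half-open span; candidate break
  points are scored by the density of the prefix (or suffix) measured
  over the distance to the first position *across* the break, so breaks
  gravitate to large gaps; the minimal such density is the segment's
  `min_density` and the recursion descends both sides. A single position
  is reported with span 1, `max_density = weight` and a `min_density`
  sentinel of 0 rather than an infinity. Reported segments are
  post-filtered to a maximum length (200 bp) and to non-overlap, keeping
  the higher `max_density`. The implementation is verified against an
  independent exhaustive recomputation for n ≤ 10 positions.

Singleton clusters are removed unless their raw tag count is at least
`keep_singletons_above = 5`; the comparison uses raw counts, not TPM,
interpreting the corresponding CAGE-toolkit argument as a tag-count
rescue. The dominant TSS is the member with maximal TPM, ties resolved
to the 5'-most position relative to the strand.

Promoter windows span `[pos − flank, pos + flank + 1)` — the TSS base
sits at index `flank` — and minus-strand windows are
reverse-complemented so all sequences read 5'→3' with a common TSS
index. The default `flank = 200` follows the study's methods section;
its results text mentions 150 nt in one place, a discrepancy the
parameter absorbs (pass `flank = 150` to match the narrower window).

## Core-promoter architecture

The element catalog (TATA, INR, DPE, MTE, M1BP) ships as an editable
tibble of consensus strings transcribed from the core-promoter
literature — the study cites but does not print its matrices, so these
defaults are configuration, not asserted facts, and PWMs can be
substituted per element. Positional elements are scanned sense-only;
factor motifs on both strands. Offsets are hit start minus TSS index;
the positional histogram reports, per bin, the percent of promoters with
at least one hit in the bin, so a positionally constrained element shows
one sharp bin and a spacing-free binder shows a flat profile (a planted
uniform-offset motif stays flat to within 3 percentage points at
n = 2000 in the tests). Class enrichment compares element presence
between two promoter sets with the same Fisher machinery as everything
else; Bonferroni correction across elements is available but off by
default, since per-element p-values are conventionally reported
uncorrected here.

## ChIP × RNA integration

The expressed-gene universe is exactly the rows of the DE table (genes
with zero reads are removed upstream of the package). Thresholds are
strict inequalities — `log2fc > 0.5`, `padj < 0.05` — matching the
"greater than" phrasing such studies use, and a missing adjusted p is
always `ns` (independent filtering leaves those genes untested).
`bound_any` means any peak overlaps any transcript span of the gene;
`bound_at_tss` requires a peak to contain a TSS coordinate. The
any-span-overlap reading of "gene overlapped a peak" is an
interpretation and is kept separate from the stricter TSS flag so either
can be used as the exposure. The target report intersects
`bound_at_tss` with `up`, sorted by fold change.

## The synthetic-data generator

`simulate_scenario()` is the package's test bed, not a fixture: every
generator is a pure function of its inputs and a seed, with per-stage
sub-seeds derived by stable hashing of (master seed, stage name) so
single stages can be reproduced in isolation. The defaults are the
standing study conditions: replicate base-pair Jaccard 0.64, 45% of
peaks at TSSs, a motif planted in 72% of consensus peaks, and a planted
bound×up odds ratio of 2.21, at desk scale — a 1 Mb, 2-chromosome
genome with 150 genes and 300 peaks per replicate, sizes chosen so the
full scenario simulates in seconds on one CPU while every downstream
stage still has enough events to estimate its statistic.

Construction choices worth knowing:

- Replicate 2 retains a whole-interval fraction `k = 2J/(1 + J)` of
  replicate 1 and adds independent non-overlapping peaks; the realized
  Jaccard (recorded in `truth`) is controlled to about ±0.05 of the
  target rather than exactly — exact base-pair control would require
  splitting intervals for no scientific gain. Downstream tests compare
  against the *realized* value, which the Jaccard estimator recovers to
  1e−9 (it is the same arithmetic on the same intervals).
- Planted motif instances draw each degenerate position uniformly from
  its class and land at `summit + Normal(0, offset_sd)` on a random
  strand. Recovery by scanning is a one-sided check: background matches
  can only add to the planted fraction (at the defaults they add a few
  percent, mostly via the short degenerate variants).
- DE status is assigned with the bound-conditional up-probabilities
  solved by `uniroot` so the *expected* sample odds ratio equals the
  planted value at the requested marginals; `padj` values are simulated
  around the 0.05 boundary, not computed from counts — model fitting is
  out of scope and the integration stage consumes thresholds only.
- Coverage is an absolute-Gaussian input baseline plus a triangular
  enrichment bump per peak — enough structure for profile machinery to
  show summit-centered maxima, with no fragment-length or GC model.

What passing tests on synthetic bundles do *not* show: real ChIP
backgrounds are not white noise, real peak width and CAGE tag-count
distributions are heavy-tailed in ways the generator only sketches, and
real promoters carry correlated element co-occurrence. The synthetic
results validate the *estimators* — that each statistic recovers a known
planted value under its own model — not field performance on any
particular organism's data.

## Numerical and degenerate-input conventions

- Fisher tables with a zero margin: p = 1, odds ratio `NaN`, warning.
- Jaccard of two empty sets is an error (0/0); one empty set gives 0.
- BPM and TPM normalization reject all-zero inputs rather than emitting
  NaNs.
- Track subtraction keeps negative values; no pseudocount, no clipping.
- Profile rows for minus-strand points are reversed so column order is
  always 5'→3'; regions clipped at contig edges contribute zeros
  (missing-data-as-zero).
- Scale-region rows shorter than one bin are filled with their mean and
  flagged with a warning.
- PWM score discretization is 1/1000 of the score range; the induced
  p-value error is bounded by the mass of one grid cell and the DP is
  tested against exhaustive enumeration for motifs up to 8 bp.
- Heatmap row ordering breaks ties by row id, making output
  deterministic.

## Known limitations

The overlap-Fisher fourth cell is a heuristic, as discussed above; use
permutation frameworks where calibrated significance matters.
Multi-sample CAGE aggregation, power-law tag normalization and
cluster-boundary trimming by cumulative distribution are out of scope.
The genome build is treated as opaque input — nothing models liftover
between assemblies. Figure rendering aims for scientific equivalence
(same matrices, same orderings), not pixel parity with the deepTools
plots it replaces.
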