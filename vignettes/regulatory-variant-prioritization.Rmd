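---
title: "Prioritizing regulatory GWAS variants: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Prioritizing regulatory GWAS variants: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(regprior)
```

Most GWAS associations for complex diseases point at non-coding haplotypes:
the lead SNP tags tens to hundreds of co-inherited proxies, any of which may
be the functional base. `regprior` implements a prioritization pipeline that
narrows such a candidate set using cell-type epigenomic maps, quantifies the
statistical enrichment of each overlap, tests motif proximity against a
randomized-matrix null, and follows candidates up with allele-specific and
eQTL models. This vignette explains the statistical models, the tunable
parameters and the design decisions that were genuinely open, and what the
synthetic-data experiments do and do not demonstrate.

## Interval model

All genomic intervals are 0-based half-open (BED convention), including SNP
positions stored as width-1 intervals. Coordinate conventions in this
field are notoriously mixed across tools; fixing one convention
end-to-end means a SNP at `pos == end` of a peak is *outside* it, adjacency
is never overlap, and `midpoints()` of an even-length interval takes the
lower-middle base (`floor((start+end)/2)`), matching common peak-summit
tooling. Overlap, merging and coverage arithmetic are delegated to
`GenomicRanges`/`IRanges` behind the `PeakSet` surface. Peaks are unstranded;
strand only matters inside motif scanning.

## LD expansion and marker selection

Lead SNPs are expanded to `leads ∪ {proxies with r² ≥ r2_min}` with the
inclusive default `r2_min = 0.8`, the conventional "high LD" cutoff.
Linkage is consumed as an input table (r², |D′|, population) as obtained
from reference-panel browsers — the package does not compute LD from
genotypes. Input tables may violate `r² ≤ D′²`; such records are counted
and reported but kept, since discarding them would silently change the
candidate set. For allelic-expression assays, a transcribed marker is
selected at `|D′| > 0.90` (falling back to `> 0.75` when nothing qualifies)
with MAF > 0.15 so that heterozygous donors are obtainable; ties break by
higher MAF, then rsid, to make selection deterministic.

## Enrichment statistics

**DHS-background contingency.** Each interval of a DNaseI-hypersensitivity
(DHS) background universe is classified by (overlaps the feature peak set by
≥ 1 bp) × (contains ≥ 1 tested SNP), giving a 2×2 table whose cells always
sum to the universe size. An interval that both overlaps the feature and
contains a SNP counts once in the joint cell. The per-DHS-interval unit of
counting is one of two defensible readings of this design (the alternative
is per-SNP counting); the full flag matrix is retained so either accounting
can be audited.

**Fisher's exact test.** One-sided (`greater`) by default, as the scientific
question is enrichment. P-values come from the hypergeometric distribution
evaluated in log space (`phyper`/`dhyper` with log-sum-exp accumulation), so
tables with cells in the hundreds of thousands neither overflow nor
underflow. The two-sided p-value sums all outcome probabilities no greater
than the observed one times `(1 + 10⁻⁷)` — the tie-tolerance convention of
standard statistical software, which the test suite verifies against both
exhaustive enumeration and `stats::fisher.test`. The odds ratio is the
sample estimate `(ad)/(bc)` with a 0.5 continuity correction on every cell
when any cell is zero, and a 95% Woolf interval. Degenerate tables (an
all-zero margin) return `p = 1` with the odds ratio flagged undefined.

**Binomial open-chromatin enrichment.** For a phenotype with `n` SNPs of
which `x` fall in open chromatin, the p-value is the upper tail
`P(X ≥ x)`, `X ~ Binomial(n, p)`, with `p` the fraction of the uniquely
mappable genome (default constant 2,630,301,437 bp, the uniquely mappable
hg19 genome) lying in open-chromatin regions containing assessed SNPs.
Fold enrichment is reported as `x/(np)`; the axis of enrichment scatter
plots in this literature is rarely given a formula, so this definition is
declared rather than inferred.

**Density profiles.** Point features (SNPs, motif-hit centers) are counted
in `bin_bp`-wide bins of signed offset to region centers across a
±`window_bp` window (defaults 100 bp bins, ±1 kb). Each feature is assigned
to its nearest center, ties to the leftmost, so no feature is counted twice.
"Global" normalization divides counts by the number of reference centers,
making profiles comparable across datasets of different sizes; a per-bin
(profile-sums-to-one) alternative is available but off by default.

## Motif scanning and the randomized-matrix null

PWM columns are normalized to probabilities, a pseudocount of 0.01 is added
and renormalized, and scores are `log2(p/background)` summed over
positions. The scan threshold for a target p-value (default 0.001, standard
genome-scanner practice) is computed by exact dynamic programming over the
score matrix discretized at 10⁻³ bits. One subtlety is load-bearing: the
*same* discretized matrix drives both the threshold computation and the
scanner, the device used by integer-scoring genome-wide scanners. If the
scanner instead compared exact scores against a discretized threshold,
words within half a granularity step of the cutoff would be classified
inconsistently; with a single shared model the hit set is exactly defined,
and the test suite verifies it against exhaustive W-mer enumeration for
W ≤ 6. Reported hit scores are therefore multiples of the granularity
(within `W·g/2` of the exact log2-odds); `score_pwm()` on a single word
remains exact.

Scans cover both strands, with reverse-strand hits reported in forward
coordinates. The null model for motif-proximity testing is a
column-permuted copy of the matrix: per-column base composition, and hence
overall composition bias, is exactly preserved while the positional word is
destroyed. The permutation is drawn uniformly from non-identity
permutations under a caller-supplied seed.

The proximity test counts real-matrix and randomized-matrix hits whose
centers fall within ±100 bp of any SNP (near band) versus 900–1000 bp away
on either flank (far band; both flanks, noted for sensitivity analysis),
and applies the one-sided Fisher test to the resulting 2×2 table. Distance
is measured SNP-position to hit-center. Hits are counted once per band
membership, not once per SNP, so overlapping near-windows of clustered
SNPs do not inflate counts.

In simulation experiments the PWM background is set to the simulated
genome's base composition, as a practitioner would configure a genome-wide
scanner; against a mismatched (uniform) background the threshold no longer
controls the per-position hit rate and background hits dilute the planted
signal.

## Super-enhancers

Peaks carrying signal are stitched when their gap is ≤ 12,500 bp
(inclusive — the boundary is undocumented in the tooling this emulates, so
the inclusive reading is declared); stitched signal is the sum of member
signals. Calling uses the rank-curve tangent rule: regions sorted by
ascending signal, both axes scaled to [0, 1], and the calls are the suffix
strictly beyond the first point where the local slope (one rank step)
exceeds 1. All-equal signals call nothing; the rule is invariant to adding
a constant to every signal. Upstream concerns — input-signal subtraction,
promoter exclusion, peak-calling FDR — are out of scope here and belong to
the peak caller.

## Allelic quantification

A genotyping assay's two fluorescence channels are calibrated on a mixing
series of homozygous DNA (8:1 … 1:8, log2 design points 3…−3) by ordinary
least squares of measured log2 intensity ratio on `log2(mix)`. All logs
are base 2 — the measurement is defined on the log2 scale, and the source
protocols are ambiguous about the base of the design-point log, so one
base is used throughout. Heterozygote cDNA and gDNA measurements are
inverted through the curve and the gDNA ratio is subtracted on the log2
scale before back-transforming (equivalent to dividing the ratios),
normalizing away probe bias; 1.0 means balance. Replicates are averaged on
the log2 scale before inversion. Imbalance is tested by a two-tailed
one-sample t-test of the normalized ratios against 1.0; constant input
equal to 1.0 returns `t = 0, p = 1` by contract. Allele-specific ChIP
compares antibody groups against a chromatin-input control with Welch's
unequal-variance t-test; groups with near-zero assay signal (an empty IgG
pulldown) are flagged and excluded rather than quantified. Testing on the
ratio scale (not log-ratio) follows the assay convention this models; it
carries a small lognormal bias whose practical effect at the default noise
level (measured type-I error ≈ 0.055–0.065 at n = 23) is visible in the
acceptance simulations.

## eQTL models

Association is an OLS regression of log2-scale expression on allele dosage
(0/1/2) with the usual slope t-test; optional covariates are supported but
default to none, since upstream normalization is assumed to have adjusted
them. The conditional analysis P(SNP₁ | SNP₂) residualizes expression on
SNP₂ and tests SNP₁ against the residuals. The source description of this
procedure can be read as "genotype onto residuals" or "residuals onto
genotype"; the slope t-test of a simple regression is symmetric in its two
variables, so both readings give the same p-value, which the test suite
asserts. Perfect collinearity (r² = 1) is flagged and yields a null result
by construction. The cis window is a query-time filter, default 2 Mb
centered on the SNP, and scan results are reported up to p ≤ 0.05.

## Prioritization funnel

Variants are flagged by 1-bp containment in open chromatin, active
enhancer and TF-binding peaks (TF = union of the supplied per-factor sets,
with per-factor flags kept for auditing); the combined set is the triple
intersection. The annotation filter keeps candidates with a functional
score category ≤ 4 and ≥ 1 bound trans-acting factor, dropping and
counting unscored candidates. Annotation scores are consumed as an input
table; no live database is queried.

## What the synthetic data emulates — and what it does not

`sim_config()` fixes the study conditions: a 1-Mb i.i.d. genome at GC 0.41
with 200 planted motif instances, 100 case + 100 control SNPs with half
the case SNPs within 100 bp of a motif center, LD blocks of 4 giving every
lead a perfect proxy, a 7-point calibration series (slope 0.95, intercept
0.1, noise sd 0.05), 23 heterozygotes at true allelic ratio 1.3 (log2
noise sd 0.1), and an n = 500 Hardy–Weinberg cohort with β = 0.4 at
MAF 0.3. Every generator is a pure function of the config seed.

Three generator choices deserve explanation:

* **Planting uses the consensus word by default** (`plant_mode =
  "consensus"`); sampling instances from the PWM is available. At a scan
  p-value of 0.001 a 7-bp matrix admits only on the order of a dozen
  words, so per-column-sampled instances are missed far more often than
  5% of the time for any realistically sharp matrix; consensus planting
  keeps planted-truth recovery a sharp (≥ 95%) contract while sampled
  planting remains available for softer, more realistic experiments.
* **The no-enrichment null draws the feature as a random subset of DHS
  intervals** (`sample_feature_subset()`). Building the feature as an
  independent random peak set and merging everything into the universe
  makes multi-peak DHS intervals systematically longer, and length then
  couples feature overlap with SNP containment — the test looks
  anti-conservative for a structural reason, not a coding one. The subset
  construction makes the two classifications exactly independent, which
  is also the biologically faithful null: one cell type's open chromatin
  is a subset of the pan-cell-type DHS universe.
* **LD tables are generated internally consistent** (`r² ≤ D′²`) even
  though the reader tolerates violations in external input.

What passing these experiments shows: the statistics are calibrated under
their nulls, planted signal of realistic effect size is detected at the
study's design sizes, and every structural invariant of the pipeline
holds. What it does not show: performance on real genomes (non-i.i.d.
sequence, repeat structure, realistic LD decay, peak-width and signal
distributions), robustness to assay artifacts beyond Gaussian intensity
noise, or the specific counts of any real dataset — reproducing a real
study's funnel requires its external data and is expressly out of scope.

## Numerical choices and degenerate inputs

* Fisher/binomial p-values in log space; `-log10(p)` is reported alongside
  `p` so vanishing tails remain comparable.
* Score discretization 10⁻³ bits; the threshold is the smallest
  *achievable* discretized score whose tail probability is ≤ the target.
* Ties: nearest-center assignment breaks leftward; proxy selection breaks
  by MAF then rsid; super-enhancer sorting is stable in signal.
* Degenerate inputs have defined outcomes rather than errors where a
  contract exists: all-zero Fisher margins (`p = 1`, OR undefined),
  constant allelic ratios equal to the expectation (`t = 0, p = 1`),
  self-conditioning eQTLs (flagged collinear, null result), all-equal
  super-enhancer signals (no calls).

## Problem sizes

The shipped experiments use the desk-scale design throughout: 20 seeded
1-Mb genomes for the motif-proximity experiment, 100 simulations for the
DHS null, 2,000 for allelic type-I error, 200 for allelic power, 500 for
eQTL coverage and 1,000 for p-value uniformity. These sizes give binomial
standard errors comfortably inside the asserted bands while every stage
remains a pure-R computation over a single in-memory genome.

```{r funnel-example}
cfg <- sim_config(seed = 7)
g <- generate_genome(cfg)
panel <- generate_snp_panel(cfg, g$motifs)
peaks <- generate_peaks(cfg, g$motifs)
causal <- names(panel$truth$near_motif)[panel$truth$near_motif]
ann <- generate_annotations(panel$case$rsid, causal, seed = 8)
funnel <- prioritization_funnel(panel$leads, panel$ld, panel$case,
                                peaks$atac, peaks$h3k27ac, peaks$tf, ann)
funnel$counts
```
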