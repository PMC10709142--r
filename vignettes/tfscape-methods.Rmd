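---
title: "tfscape: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{tfscape: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tfscape)
```

tfscape integrates five kinds of evidence around a 2x2 perturbation design
— a transcription factor overexpressed (or not) crossed with hormone
stimulation (or hormone deprivation), giving the conditions mock, mockE2,
MAF and MAFE2 — to characterise how the factor rewires the hormone
response: chromatin accessibility (ATAC-like count matrices over a
consensus peak set), factor and histone-mark binding sites (ChIP-like peak
sets), transcript abundance (RNA-seq-like count matrices), a
proximity-labeling interactome (bait–prey spectral-count tables), and
clinical cohorts (expression plus time-to-event). This vignette explains
each model, the tunable parameters, and the choices made where the design
was genuinely open.

## Coordinates and annotation

All intervals are 0-based half-open. BED input/output is native; GTF gene
lines are converted on read. A peak is annotated by its **midpoint**:

* `promoter-TSS` if the midpoint lies within 2,000 bp of any TSS — both
  edges inclusive, so a midpoint exactly 2,000 bp away still counts;
* otherwise `gene-body` if the midpoint falls inside any gene span (gene
  sub-structure such as exons and UTRs is deliberately collapsed to the
  span, since the three-way categorisation is all downstream stages use);
* otherwise `intergenic`.

The nearest gene minimises |midpoint − TSS|, with ties broken by
lexicographic gene id so results are reproducible. Upstream/downstream
sign follows gene orientation (positive downstream). Whether a peak
should be represented by its midpoint or a coverage summit is not
determined by the interfaces we consume; the midpoint is used everywhere
and is the documented convention. Interval overlap carries a `max_gap`
tolerance (default 100 bp for histone-mark overlap); two intervals with a
gap of exactly `max_gap` overlap, consistent with `IRanges::findOverlaps`.

## Contrast statistics and cluster rules

Counts are normalised with median-of-ratios size factors (geometric-mean
reference, computed on features positive in every sample). Features with
mean raw count at or below 5 are discarded before gene-level testing.

Per feature we fit a negative-binomial log-linear model over the four
condition means (optionally plus an additive batch term for a sequencing
round), with `log(size factor)` offsets and variance
`mu + alpha * mu^2`. Five contrasts are reported: MAF vs mock, mockE2 vs
mock, MAFE2 vs MAF, MAFE2 vs mockE2 and MAFE2 vs mock.

Two numerical choices matter at small replicate numbers (the default
scenario has 3 per condition):

* **Dispersion.** The raw per-feature method-of-moments estimate of
  `alpha` is very noisy at 12 samples and, because all five contrasts of a
  feature share it, its noise couples the contrasts: conjunction rules
  ("beyond the cutoff in *both* contrasts") then fire far more often than
  independent tails predict. The default therefore pools the raw estimates
  through a lowess trend against the log mean and uses the trend value
  (`dispersion = "trended"`); `"per-feature"` is available for data whose
  dispersions genuinely vary feature to feature, at a documented
  calibration cost.
* **Calibration.** The Wald ratio with an estimated dispersion has
  t-like, not normal, tails. The reported statistic is the raw ratio
  passed through a t reference with the model's residual degrees of
  freedom and mapped back to the standard-normal scale, so `|stat| > 2`
  keeps its nominal meaning and `p = 2 * pnorm(-|stat|)` is consistent
  with the statistic by construction. On a 2,000-feature null simulation
  this yields a tail fraction beyond |2| of about 0.04 and a spurious
  cluster rate of about 0.5%, inside the independent-conjunction bound.

Cluster rules are conjunctions at `|stat| > 2` (strict) or `> 1.5`
(relaxed): clusters A/B require the factor contrasts (MAF vs mock **and**
MAFE2 vs mockE2) beyond the cutoff, C/D the hormone contrasts (MAFE2 vs
MAF **and** mockE2 vs mock), E/F the interaction contrasts (MAFE2 vs MAF
**and** MAFE2 vs mockE2); positive for A/C/E, negative for B/D/F. Gene
clusters 1–6 use the identical machinery (1 is A, ..., 6 is F); no
separate numeric rule is published for genes, so reusing the peak cutoff
is an explicit assumption of this package. When several rules fire we
assign with priority E/F, then A/B, then C/D — the interaction clusters
are the scientific focus — and also report every fired rule, since
exclusivity is not inherent in the rules. The relaxed variant restricts
to promoter-TSS peaks and additionally requires breadth
(`log10` width) > 3 for the opening clusters A and E.

## Permutation enrichment tests

A cluster's annotation-category percentage (or histone-mark overlap
percentage) is compared against random same-size subsets of the consensus
peaks, drawn without replacement — the null is "a random subset of the
consensus universe", which preserves peak widths automatically. The
one-tailed p-value uses the add-one convention
`p = (1 + #{null >= observed}) / (1 + n_iter)` (default 1,000
iterations), so p is never zero and the test is valid by construction.
On instances small enough to enumerate, `exhaustive = TRUE` replaces
sampling by the complete subset enumeration and returns the exact tail
probability; the test suite pins the sampled version against it. Breadth
comparisons between annotation groups use the two-sided Wilcoxon rank-sum
test (tie-corrected normal approximation when ties preclude the exact
distribution; fully tied inputs report p = 1).

## TSS-proximity curves and meta-profiles

The enrichment curve reports the cumulative percentage of binding sites
within 10, 20, ..., 100 kb of any target-gene TSS, against `n_perm = 100`
random draws of equally many genes from a comparison pool; the envelope
is the 5th-largest permuted value per distance (an empirical ~95% upper
envelope; the rank is a parameter). The comparison pool is a user input —
"constitutively expressed genes" is a cohort-specific notion; synthetic
runs use flat-expression genes.

The TSS meta-profile aggregates size-factor-normalised `log2(1 + q)`
signal into 25-bp bins of signed TSS distance for peaks within 25 kb
(boundary included), averages per condition and subtracts the mock
condition. A GCV-chosen cubic smoothing spline is available for display
only; raw bin means are always returned.

## Promoter–enhancer links

For every (peak, gene) pair with midpoint-to-TSS distance at most 500 kb,
the Spearman correlation of peak signal and gene expression across shared
samples is computed (rank-based, hence invariant to monotone transforms);
p-values come from the t approximation on the rank correlation, are
BH-adjusted over all tested pairs, and pairs with adjusted p <= 0.05 and
positive correlation become links. The upstream methodology this mirrors
does not publish its exact thresholds, so all three choices (correlation
type, cutoff, sign restriction) are configurable, and a precomputed link
table can be supplied directly. Link enrichment of a candidate peak set
is again a one-tailed permutation test (default 10,000 draws of
equal-size peak sets from the universe, without replacement) whose null
mean equals the hypergeometric expectation — a property the tests check.

## Motif overrepresentation and super-enhancers

Motif matching itself is out of scope; match positions are an input (a
toy exact-string scanner would be trivial, but published matrix scanners
are the practical source). Under uniform genome-wide placement the match
count in regions totalling `r` bp of a `G` bp genome is binomial with
`p = r/G` over the `n` genome-wide matches, giving `E = np` and
`S = sqrt(np(1-p))` — binomial rather than Poisson because the
genome-wide match count is fixed; at genome scale the difference is
negligible. The continuity-corrected z-score is `z = (X − E − 0.5)/S` and
the fold factor `X/E`. Ten thousand uniform-placement simulations put z
within 0.05 of standard normal in both mean and SD.

Super-enhancer candidates stitch histone-acetylation peaks within
12.5 kb (single linkage); peaks fully contained in a TSS ± 2 kb window
are excluded beforehand (straddling peaks are kept). Stitched domains are
scored by target minus input signal, floored at zero; the signal over a
stitched span is the **sum** over constituents (configurable — the mean
is equally defensible, the sum matches rank-curve practice). The
super-enhancer cutoff is the classic tangent rule: scale ranks and scores
to [0, 1] and cut where the curve's slope reaches 1 (equivalently, the
point of maximal vertical distance below the diagonal); the flags are
invariant to uniform signal rescaling, and a degenerate all-equal curve
yields no super-enhancers.

## Interactome filtering and the bait network

Bait–prey tables follow the SAINT output convention. Dual search engines
are merged by the per-replicate maximum; the top `k = 3` replicates per
pair are kept; high-confidence interactors satisfy BFDR <= 0.02 and fold
change >= 3, both boundaries inclusive (published descriptions of this
filter mix "<" and "<=", so the thresholds are parameters). The bait
network over four baits (two isoforms x two tag positions) takes the
within-isoform intersections, their union as the network, and the
four-way intersection; inclusion–exclusion holds exactly and is asserted
on arbitrary inputs. Identifying the four-way intersection with
"common to all four conditions" is the arithmetically consistent reading
of the published set sizes (92 + 105 − 71 = 126).

## Signature survival analysis

The tested signature is the set of cluster-1 (factor-upregulated) genes
whose nearest-TSS annotation target is hit by a binding site in **both**
binding conditions; the association distance is configurable (default:
nearest gene at any distance, since no cutoff is published). Samples are
scored by the mean of genewise z-scored log expression — the summary
statistic is not published; the mean z-score is the simplest choice and
is configurable by supplying scores directly. Stratification is strict:
`low` iff score < mean − 1 SD, which is invariant to affine score
transforms. Survival is compared with Kaplan–Meier estimates and the
two-sided log-rank test (1 df) via the `survival` package; a group with
zero events is reported with a note rather than an error. Cohort
expression can be residualised genewise against clinical covariates
(ordinary least squares, recentred at gene means) before scoring.

## The synthetic-data module

Every generator draws from a `synthetic_scenario()`, whose defaults *are*
the study conditions of the package: 2,000 genes and 5,000 consensus
peaks on a 4 x 25 Mb genome, 3 replicates per condition,
negative-binomial dispersion 0.1, planted |log2 FC| = 2 for 50 genes and
80 peaks per cluster, promoter fractions 0.8 (cluster peaks) vs 0.2
(background), histone-mark overlap 0.7 vs 0.2, link correlation 0.7
across 50 samples for 100 planted pairs, and a survival cohort of 200
with hazard ratio 3 for the low-signature sixth of patients
(exponential event times, independent uniform censoring over 120 months,
~60% events). Planted differential features receive moderately high
baseline means (log-normal around 200) — the realistic regime in which a
3-replicate design can detect a four-fold change. Everything is
reproducible: generators derive fixed streams from the scenario seed, and
each written dataset carries a ground-truth JSON sidecar consumed by the
recovery tests.

What the generators do **not** emulate: read-level data (no FASTQ,
fragment-size or GC structure), correlated gene–gene expression beyond
the planted factors, peak-width/signal coupling, batch effects (the
design supports a batch column, but none is planted by default), and
informative censoring. Passing recovery tests therefore demonstrates that
the *rules and tests* behave as specified under their stated models — not
that real data meet those models.

## Problem sizes and runtime choices

The test suite and the acceptance script run the default scenario
(2,000 genes / 5,000 peaks), 500 survival power simulations and 1,000
null simulations at n = 200, 10,000 motif-placement simulations, and
1,000–10,000-iteration permutation tests; these sizes give Monte-Carlo
errors comfortably below the decision margins they support while keeping
a full run in the minutes range. Exhaustive enumeration modes are
restricted to instances with at most ~2x10^5 subsets.

## Known limitations

* The contrast statistic is a calibrated NB Wald statistic, not a
  re-implementation of any published tool; absolute values differ from
  shrinkage-based estimators, which is why externally produced contrast
  tables are accepted everywhere cluster rules are applied.
* Trended dispersion assumes a smooth mean–dispersion relationship;
  datasets with genuinely heterogeneous per-feature dispersion should use
  `dispersion = "per-feature"` and expect conservative-to-liberal
  miscalibration at few replicates.
* Multi-isoform TSSs, exon-level annotation and liftover are out of
  scope; one TSS per gene.
* The link builder tests all pairs within the window; with very dense
  peak sets the BH family grows accordingly, which is the intended
  (conservative) behaviour.
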