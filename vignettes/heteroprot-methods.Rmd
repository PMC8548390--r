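---
title: "Methods: inheritance-pattern analysis of hybrid proteomes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: inheritance-pattern analysis of hybrid proteomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(heteroprot)
```

## The design and the question

A heterosis proteomics experiment measures a female parent, a male parent
and their F1 hybrid — a *trio* — with biological replicates (typically
three) on a label-free quantification platform. The quantified output is
a proteins × samples abundance matrix of strictly positive intensities.
Two questions drive the analysis:

1. Which proteins differ between genotypes (DEPs), and in which
   direction?
2. For proteins differential between the hybrid and its parents, is the
   hybrid level *additive* (near the mid-parent value), *dominant* (near
   one parent) or *over-/under-dominant* (outside the parental range)?

The balance between these inheritance modes, together with trait-level
heterosis indices, is the interpretive core: a preponderance of
over-dominant accumulation argues that the hybrid's advantage is driven
by expression levels unreachable by either parent.

## Differential expression

Per protein and pairwise comparison we use a pooled-variance two-sided
Student t-test with `df = n1 + n2 - 2`. With three replicates per group,
per-group variance estimates are too unstable for Welch's correction to
help; pooling is the conventional choice at this depth. Testing is done
on log2 abundances by default (intensity data are approximately lognormal,
so the t-test's normality assumption is far more plausible on the log
scale); the reported fold change is always the ratio of raw-scale group
means, because the classification thresholds below are defined on that
scale. `p_adj` is Benjamini–Hochberg across all testable proteins of a
comparison, and `use_fdr` selects whether the significance flag uses the
adjusted (default) or raw p-value — both conventions appear in practice
and the choice is deliberately exposed rather than hidden.

Degenerate inputs are handled explicitly: when the pooled variance is
zero the statistic is defined as `t = 0, p = 1` for a zero mean
difference and `t = ±Inf, p = 0` otherwise. This makes noise-free
simulated data (a useful validation limit) flow through the caller
instead of erroring, and is the reason the test is implemented directly
rather than via `stats::t.test()`, which refuses essentially constant
data. The implementation is cross-checked against `t.test(var.equal =
TRUE)` in the test suite.

Proteins with fewer than two observed replicates in either group are
excluded from that comparison and reported in a `skipped` attribute; the
jointly quantified set used as the percentage denominator is the
complete-case subset (`filter_complete_cases()`), i.e. proteins observed
in every sample. Whether partial within-genotype missingness should be
tolerated is genuinely ambiguous for this design; complete-case is the
strictest and most reproducible reading.

## The classification rule table

Classification uses three ratios per protein: `F1/MP`, `F1/HP`, `F1/LP`
(hybrid mean over mid-, high- and low-parent mean). Parameters, with
defaults in `pattern_params()`:

* `upper = 1.5`, `lower = 0.67` — the fold-change pair bounding the
  additive window. They are reciprocal to within rounding
  (1/1.5 = 0.667), which is why the window is symmetric on the log scale.
* `band = 0.10` — a proportional band around each threshold separating
  "dominant" (near the threshold) from "over-/under-dominant" (beyond
  it). The derived cut points are 1.65 = 1.5 × 1.1 and
  0.603 = 0.67 × 0.9.

Rules are evaluated in order (first match wins): additive window on
`F1/MP`; then the up-bands on `F1/HP` (≥ 1.65 over-dominant,
[1.5, 1.65) dominant-high); then the down-bands (≤ 0.603
under-dominant, (0.603, 0.67] dominant-low). Boundary conventions: the
additive window is open; the outer bands are closed at their cut points.
A non-additive protein matching no band — possible because the additive
test uses MP while the bands use a parent — receives an explicit
`partial_nonadditive` label rather than being dropped silently.

### Two readings of the down-bands (`mode`)

The conventional verbal definition of the down-regulated bands names the
*high* parent as reference for every ratio. Read literally, "low-parent
expression" would then mean F1/HP ∈ (0.603, 0.67] — a hybrid *below*
the high parent but not necessarily near the low parent, which is
biologically incongruent and, whenever the parents differ by more than
about 1.25-fold, unreachable (such ratios fall inside the additive
F1/MP window first). We therefore ship both readings:

* `mode = "literal"` (default): all ratios against HP, matching the
  verbal rule table exactly;
* `mode = "reconstructed"`: down-bands against LP, so "low-parent"
  means "near the low parent" and all six classes are realisable for
  any parental divergence.

The two modes differ only for proteins in the down-bands; every test of
the classifier runs in both.

Aggregation for reporting pools rule 2 with rule 4 as *over-dominant*
(up + down) and rule 3 with rule 5 as *dominant*, the grouping used in
heterosis-proteomics summaries; the five headline percentages
(non-additive / classified, over-dominant and dominant / non-additive,
over-dominant / classified, up / over-dominant) are rounded half away
from zero to one decimal. Half-away-from-zero (rather than base R's
half-to-even) matches how such tables are conventionally printed;
`percentage()` exposes it directly. The set of proteins classified is
the union of the two hybrid-vs-parent DEP sets — the natural reading of
"DEPs between the hybrid and its parents".

## Heterosis indices

With trait means F1, HP = max(P1, P2), LP = min(P1, P2) and
MP = (P1 + P2)/2:

OPH = (F1 − HP)/HP × 100, MPH = (F1 − MP)/MP × 100,
BPH = (F1 − LP)/LP × 100.

Genotype means are arithmetic means over replicates. The three
percentages are scale-invariant, symmetric in the parents, and ordered
OPH ≤ MPH ≤ BPH whenever F1 > 0 and LP > 0 (the numerator decreases and
the denominator increases together). A zero parental reference raises an
error naming the undefined index. Pairwise genotype differences are
tested with the same pooled t as the proteomics module — a deliberate
simplification of multiple-range letter groupings, which add a
multiple-comparison convention without changing any reported index.

## The synthetic-data generator

`simulate_quant()` emulates the trio design with planted ground truth.
Per protein:

* a baseline log-median is drawn from N(log 1e6, 1) — intensities
  spanning a few orders of magnitude, as in label-free data;
* non-null proteins get parent medians separated by `parent_fold`
  (default 2, a typical clearly-divergent fold) with the high parent
  assigned at random;
* the hybrid median is a pattern-specific multiple of its reference:
  MP for additive; 1.575 × HP and 0.6365 × (reference) for the dominant
  bands (band midpoints); 2.0 × HP and 0.45 × (reference) for the
  over-/under-dominant bands (comfortably beyond the cuts);
* replicates are `median × exp(N(0, σ))` with `σ = sqrt(log(1 + cv²))`,
  so `cv` is the coefficient of variation of the multiplicative noise
  and the planted value is the log-scale *median* (the arithmetic mean
  is `median × exp(σ²/2)`; ratios of means are unaffected, which is why
  planting on the median is consistent with mean-ratio classification).

The default `cv = 0.2` reflects a typical between-replicate spread for
label-free protein quantification; the default mix plants 13% of
proteins as non-null (3% additive, 2% + 1% dominant bands, 5% + 2%
over-/under-dominant), echoing the class balance seen in real trio
studies where over-dominant calls dominate the non-additive fraction.
Planting follows the `mode = "reconstructed"` rule table by default
because all six classes are realisable there; an infeasible combination
(e.g. a literal-mode low-parent class with 2-fold parents) is rejected
at configuration time rather than silently planting mislabelled truth.

Reproducibility: one integer seed drives per-protein substreams derived
from a counter, so enlarging `n_proteins` extends the panel without
reshuffling earlier proteins, and the caller's RNG state is restored on
exit.

What the generator does *not* emulate: peptide-level roll-up,
missingness mechanisms, batch or run-order effects, and
intensity-dependent variance. Passing recovery tests on this generator
therefore demonstrates the correctness of the statistical pipeline under
its stated noise model, not robustness to those real-data pathologies.

### Recovery and its limits

At `cv = 0` recovery of planted labels is exact by construction. At
`cv = 0.05` with three replicates the dominant bands are intrinsically
hard: the band [1.5, 1.65) is only ±0.047 wide in log units while the
ratio of two 3-replicate means has a log-scale standard deviation of
about 0.041, so roughly a quarter of true dominant-band proteins
fluctuate across a cut. Overall recovery then depends on the class mix;
with the default mix (~23% of non-null mass in the bounded bands) it
sits near 95%, with essentially all errors confined to
dominant-vs-neighbour swaps, while additive and over-/under-dominant
classes recover almost perfectly.

## Supporting operations

*Venn partition* is exact set algebra over the three DEP id sets; shared
fractions are reported as (pair-exclusive + triple)/|denominator| to two
decimals. *Enrichment* is the one-sided hypergeometric tail
(`phyper`, the Fisher over-representation construction) with BH across
terms, against a background defaulting to all quantified proteins.
*Clustering* is UPGMA on Euclidean distances via `stats::hclust`
(average linkage on a metric gives monotone merge heights; ties are
resolved deterministically by dissimilarity order, which on generic data
coincides with any fixed-index convention); optional per-protein
z-scoring is off by default since heat-map scaling conventions vary.
*qPCR* follows Livak: replicate Ct values are averaged on the Ct scale
before exponentiation, and the mid-parent calibrator uses the mean of
the two parents' ΔCt, so hybrid expression is read relative to the
mid-parent level. No amplification-efficiency correction is applied.

## Numerical choices and problem sizes

Rounding of printed percentages is half-away-from-zero
(`round_half_away()`), implemented as `floor(|x|·10^d + 0.5)` on exact
decimal targets. The classifier's boundary comparisons are plain
floating-point `>=`/`<=` against cut points computed once from the
parameters; tests that probe exact boundaries construct inputs whose
ratios are exactly representable (power-of-two parent means).

Validation throughout the package uses 2000-protein, 3-replicate
simulations — large enough that empirical rates (type-I error ≈ 0.05 on
all-null matrices, recovery fractions) are stable to a percent or two,
small enough that the whole suite runs in seconds. Property checks on
the classifier use 10^5 random abundance triples per rule-reading mode.

## Known limitations

* The literal rule reading cannot produce `low_parent` calls for
  clearly divergent parents; use `mode = "reconstructed"` when that
  class matters.
* BH adjustment is not idempotent (re-adjusting adjusted values changes
  them); adjusted p-values should be computed once, from raw p-values.
* With three replicates the dominant bands are narrow relative to
  realistic noise; counts in those classes should be read as
  band-membership estimates, not sharp categories.
* Complete-case filtering can discard many proteins on sparse matrices;
  no imputation is offered by design.
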