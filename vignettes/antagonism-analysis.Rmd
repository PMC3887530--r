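---
title: "Methods: antagonistic germline regulation analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: antagonistic germline regulation analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mesdrm)
```

# The problem and the design

In the *C. elegans* hermaphrodite germline, the X chromosomes are kept
partially repressed. The histone methyltransferase MES-4 and the DRM
transcription-factor complex (here represented by its subunit LIN-54)
regulate overlapping gene sets in opposite directions: genes derepressed
when MES-4 is lost are re-repressed when LIN-54 is additionally lost, and
vice versa. The experimental design that exposes this antagonism is a
four-genotype expression study — wild type (WT), *mes-4*, *lin-54*, and
the *lin-54*; *mes-4* double mutant — with three biological replicates
each, assayed as log2 expression.

`mesdrm` implements the analysis of such a design end to end, and ships a
synthetic-data generator that plants the assumed structure so that every
inference step can be validated by recovering known ground truth.

# Differential expression model

Each reported comparison (mes-4 vs WT, lin-54 vs WT, double vs mes-4,
double vs lin-54, double vs WT) is an independent two-group fit: per gene,
`log2FC = mean(B) − mean(A)` and the pooled within-group variance `s_g²`
on `d_g = n_A + n_B − 2` degrees of freedom. A four-genotype linear model
with contrasts would pool residual variance across all genotypes; we chose
independent two-group fits because each comparison is reported with its
own significance calls, and the two routes coincide in expectation under
the homoscedastic model the generator plants.

The moderated t-statistic shrinks each `s_g²` toward a prior variance
under the scaled-inverse-chi-square hierarchy:

* prior: `σ_g² ~ s0² · d0 / χ²(d0)`;
* posterior: `s̃_g² = (d0·s0² + d_g·s_g²) / (d0 + d_g)`;
* statistic: `t_g = log2FC / (s̃_g · √(1/n_A + 1/n_B))` on `d0 + d_g`
  degrees of freedom.

`(d0, s0²)` are estimated by the method of moments on `log s_g²`, using
the digamma/trigamma moment identities; the trigamma equation is inverted
by Newton iteration to a tolerance of 1e-8. When the empirical dispersion
of `log s_g²` does not exceed its sampling component the prior is
degenerate: `d0 = ∞`, all posterior variances equal `s0²`, and p-values
are normal. Genes with `s_g² = 0` are excluded from hyperparameter
estimation but still receive a strictly positive `s̃_g²`, so no t-statistic
is infinite in practice; should `s̃ = 0` occur with a nonzero fold change,
p is set to 0 with a warning. The test suite cross-checks the whole
moderation path against limma's independent implementation.

## q-values

False discovery rates are Storey q-values, computed within each contrast
(not pooled across contrasts, since each comparison reports its own
counts). `π₀(λ) = #{p > λ}/(m(1−λ))` is evaluated on the grid
λ = 0.05, …, 0.95 and smoothed; the smoothed value at λ = 0.95, clipped to
(0, 1], is π₀. The default smoother is a cubic polynomial; a smoothing
spline (`pi0_method = "spline"`) is an accepted alternative, and with
fewer than 100 p-values smoothing is skipped and π₀ = 1, which reduces
q-values to Benjamini–Hochberg. The q-value of the i-th ordered p-value is
`min_{j ≥ i} π₀·m·p_(j)/j`, capped at 1. Significance is `q ≤ 0.05` for
every comparison.

# Gene classes and overlap statistics

The antagonistic classes are intersections of significance calls on a
shared gene universe:

* **X-up**: X-linked, up in mes-4 vs WT, down in double vs mes-4;
* **A-up**: autosomal, the same sign pattern;
* **A-down**: autosomal, the mirrored pattern.

Genes significant in both contrasts with the same sign form the
non-antagonistic remainder. Genes with a fold change of exactly zero carry
no direction and never enter a directional set. Overlap significance is
the exact upper hypergeometric tail, evaluated in log space so that
overlaps with p far below double-precision underflow are still reported as
finite `log10_p`.

The universe for an overlap or enrichment test is a genuine analysis
choice that the upstream study leaves open; our default is the assayed
genes of the relevant chromosome class (X-linked genes for X-up-style
tests, autosomal genes for A-up/A-down-style tests), recorded in each
result's provenance and overridable everywhere a universe is accepted.

# Restoration and profiles

Fold-change profiles report, per gene, `log2FC(genotype) = mean over the
genotype's replicates − mean over WT replicates`, with box statistics at
the 2.5/25/50/75/97.5 percentiles. The WT reference entry holds the
per-replicate deviations from each gene's WT mean — the natural "WT box"
centred on zero; a leave-one-out variant would widen it slightly but
requires dropping a replicate, and the per-replicate form is what the
profile's t-tests use anyway.

The restoration test compares each mutant's replicate-averaged per-gene
expression against WT by a two-sample, equal-variance Student's t-test,
pooling genes as observations (a paired-by-gene variant is available via
`paired = TRUE`; pairing is more sensitive but changes the null being
tested, so the unpaired pooled form is the default). The verdict is
**restored** iff both single mutants differ at α = 0.001 with
opposite-signed median fold changes and the double mutant does not differ.
Because genes are the observations, power scales with set size: sets of
~100 genes with 1 log2-unit shifts are called decisively, while sets of a
few dozen genes may fail the single-mutant criterion at α = 0.001 — a
deliberate property of the fixed-α rule, not a defect.

# ChIP binding

Intensity tracks are scaled to a raw median absolute deviation of exactly
1 (no 1.4826 consistency constant — the literal reading of "MAD = 1") and
then shifted so the median is exactly 1. Peak processing:

* **Replicate consistency** retains peaks of a designated reference
  replicate that overlap a peak in at least one other replicate by ≥1 bp
  (threshold configurable); the reference replicate's coordinates are kept
  rather than merged, so retained peaks are verbatim subsets of the input.
* **Promoter binding**: a gene is bound when a *single* peak overlaps the
  window TSS±500 bp by ≥200 bp. The per-peak rule means two abutting
  150 bp fragments do not qualify even though their union would; this is
  intentional, documented, and tested.
* **Body binding**: coverage of the gene body by the union of peaks
  ≥ 50% by default. The factor-specific definitions used upstream are
  delegated to prior work; the coverage rule is this package's explicit
  stand-in, recorded in each call's provenance.

Coordinates are 1-based inclusive inside the package; BED input/output is
0-based half-open, converted only at the file boundary, and a sorted BED3
file round-trips byte-identically.

# The synthetic-data generator

`simulate_experiment()` emulates the study design: 6000 genes spread over
chromosomes I–V and X in realistic proportions, four genotypes × 3
replicates, per-gene Gaussian baselines (mean 7, sd 1.5 log2 units), and a
planted class structure —

* X-up and A-up genes: +1.0 log2 units in mes-4, −1.0 in lin-54, 0 in the
  double mutant (a `double_restoration` knob re-introduces a fraction of
  the mes-4 effect for partial-restoration scenarios);
* A-down genes: the mirrored pattern;
* `other_de` genes: the same direction in every mutant (non-antagonistic,
  progressive in the double), planted so that the classifier's remainder
  category has substance;
* 200 genes per antagonistic class and 100 same-sign genes by default.

Replicate noise is i.i.d. Gaussian per gene with variances drawn from the
scaled-inverse-chi-square hierarchy (prior df 4, prior scale 0.25² log2
units²) — exactly the model the moderated t assumes, which makes
hyperparameter recovery a meaningful test. X-linked baselines are lowered
by 0.5 log2 units (`x_dampening`), emulating germline X repression at the
absolute-expression level. Detection calls are thresholded on the true
baseline (Absent below 6 − 0.5, Marginal within ±0.5 of 6, Present above)
with 5% uniform label noise. Expression-category labels
(germline-specific, germline-enriched, ubiquitous, soma-specific, other)
are drawn conditional on the planted class, biased so A-down is
germline-weighted and A-up soma/ubiquitous-weighted; promoter-binding
flags are Bernoulli with probability 0.8 at germline-category genes vs
0.05 background, for all three factors (MES-4, LIN-54, EFL-1), which
yields strong co-binding and class-level binding enrichment. Simulated
MES-4 peaks span the full gene body so both promoter- and body-binding
rules recover the flags; decoy peaks are placed uniformly at 2 per Mb.

All randomness flows from one master seed through fixed substreams per
data product, so regenerating one product never perturbs another and
identical seeds give identical written fixtures.

What the generator does **not** emulate: probe-level microarray artifacts
(RMA, mas5calls internals), intensity-dependent variance trends,
correlated noise between replicates or genes, read-level ChIP signal, and
genome sequence. Passing recovery tests therefore demonstrates that the
analysis logic is correct under its own statistical assumptions — not that
those assumptions hold on any particular real data set.

# Effect sizes, recovery, and what the tests show

The upstream literature reports significance counts but not effect-size
magnitudes, so the planted 1.0 log2-unit effect is a free parameter of the
generator, chosen as a typical "clear misregulation" magnitude. Under the
default conditions the intersection rule (significant in *both* defining
contrasts at q ≤ 0.05, n = 3) recovers planted classes with sensitivity
around 0.55–0.65 and precision ≥ 0.98 — the double significance
requirement squares the per-contrast miss rate, so partial sensitivity at
very high precision is the expected operating point. Test thresholds
(sensitivity ≥ 0.40, precision ≥ 0.95) were frozen in advance from an
independent Monte-Carlo evaluation of the same rule.

The fold-change anti-correlation between mes-4 vs WT and double vs mes-4
is slope ≈ −1 only when all significant-in-both genes are antagonistic;
the default design's same-sign class pulls the pooled slope toward ≈
−0.65. The near-(−1) slope check therefore runs on the cancellation-only
configuration (`other_de = 0`), where observed slopes are −0.97 to −0.99.

Quantile normalization averages order statistics; ties share the mean of
their tied ranks' reference values. With ties present, exact idempotence
and exact distribution equality across columns hold only up to the tie
groups (averaging tied values perturbs a column's empirical distribution
by construction); continuous expression data has no ties almost surely.

# Problem sizes

The shipped tests and the acceptance script run entirely on simulated
data at desk scale: the default 6000-gene design for recovery and
restoration, 5000-gene null designs (10–20 seeds) for FDR calibration,
10,000 draws for hyperparameter recovery, and randomized toy genomes
(≥1000 gene-level cases) for brute-force equivalence of the interval
rules. A full test run takes well under a minute of CPU.

# Known limitations

* Missing values are rejected, not imputed (complete arrays assumed).
* No multi-factor linear models, array weights, or intensity-dependent
  prior-variance trends.
* Genome-assembly liftover is out of scope; all coordinate inputs must
  share one assembly.
* The restoration verdict is binary at a fixed α; it does not quantify
  partial restoration (the profiles themselves do).
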