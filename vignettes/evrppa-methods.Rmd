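---
title: "Methods: RPPA analysis of extracellular-vesicle protein cargo"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: RPPA analysis of extracellular-vesicle protein cargo}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(evrppa)
```

## The measurement model

A reverse-phase protein microarray prints each sample's lysate as a
small spot on a nitrocellulose slide; one antibody probes one slide, so
an experiment with *E* endpoints and *S* samples produces *E* slides
each carrying every sample. `evrppa` models the recorded fluorescence
of a spot as the sum of three components:

* a **local background** around the spot (optics, substrate),
* a **nonspecific signal** from the detection chain itself — measured
  directly on a negative-control slide incubated with secondary
  antibody only, and
* the **specific signal**, proportional to the amount of analyte
  captured, which scales with the print concentration (a 0.125 mg/ml
  spot carries one quarter of the protein of a 0.5 mg/ml spot) and
  with the sample's overall protein loading.

The normalization chain inverts this model step by step, in a fixed
order: local background subtraction, negative-control subtraction,
technical-replicate averaging, and total-protein normalization against
the Sypro channel. Two numerical conventions matter:

* **Flooring at zero.** Both subtraction steps clip negative
  intermediates to 0. A.U. intensities are non-negative by
  construction, and a below-background spot carries no usable signal.
* **Total-protein ratio.** The Sypro correction divides by the
  sample's *relative* loading, `sypro_sample / median(sypro)`, so a
  sample at median loading is unchanged and the matrix keeps its
  original scale. A regression-based alternative was considered and
  rejected as the less common convention; the ratio form also gives
  the exact loading-invariance property the tests verify.

Negative-control matching defaults to per-spot (sample, antibody,
concentration, replicate); a per-antibody-mean variant is available via
`negctrl_method` because acquisition software differs on this point and
neither choice can be recovered from a normalized matrix after the
fact. The analysis matrix uses the 0.5 mg/ml print by default; the
0.125 mg/ml print is retained in the spot table for linearity checks.

## Absolute calibration and detection limits

Dilution series of a synthetic peptide are fit by ordinary least
squares in log-log space: `log10(I) = b + m·log10(amount)`, with the
replicates entered individually rather than averaged — the replicate
scatter is real information for the fit's standard errors. Non-positive
intensities cannot enter the log and are dropped with a warning rather
than floored; flooring would place phantom points at −∞.

Inverse prediction `amount = 10^((log10(I) − b)/m)` is exact by
construction; the package's round-trip tests require agreement to
1e−9 relative. Queries mapping outside the calibrated amount range are
flagged (`below_curve` / `above_curve`) and never suppressed: "detectable
but below the lowest dilution point" is a scientifically meaningful
outcome for EV analytes, which often sit below the picogram range.

The limit of detection formalizes "detectable over background" for
mixture series of a marker-positive and a marker-negative EV source.
Defaults: a fraction is detected when ≥ 2 of 3 replicates exceed the
background mean + 3 SD, and the LOD is the smallest nonzero detected
fraction with *no detection gap above it* — an isolated low-fraction
excursion does not count. Both k and the replicate quorum are
arguments; the LOD is monotone in k by construction.

## Cohort statistics

Group comparisons use two-sided Student's t or Wilcoxon rank-sum tests
with `log2FC = log2(mean_A/mean_B)` on arithmetic means of A.U. values.
Raw p ≤ α (default 0.05) defines significance, with BH q-values
reported alongside as auxiliary — the primary/auxiliary split keeps the
per-comparison semantics simple while still exposing multiplicity
information. Wilcoxon p-values use the normal approximation without
continuity correction so a fully tied comparison returns exactly p = 1.
Significant-set overlaps are decomposed UpSet-style: counts of
endpoints significant in *exactly* each combination, which partition
the union — a property the tests assert on random set systems.

The clinical rules are deterministic: risk stratification over the
Gleason × pTNM grid (low: Gleason 6 and ≤ T2a; low/intermediate:
Gleason ≤ 7(3+4) and T2b–T2c; high: 7(4+3) with T2c and anything
≥ T3a, with 7(3+4) ordered below 7(4+3)). Grid cells the rule does not
cover — e.g. Gleason 8 with T2a — return `"unclassified"` rather than a
guessed class; a silent default would fabricate clinical categories.
The PSA gray zone is the inclusive 4–10 ng/mL window, and percentile
over-expression flags use the linear-interpolation percentile
(`quantile` type 7) with a strictly-greater rule, so a constant
endpoint flags nobody.

## ROC analysis and composite signatures

The AUC is the tie-aware empirical (Mann–Whitney) statistic computed
from midranks; the suite verifies equality with explicit pair counting
to 1e−12 on every labeling of score vectors up to length 12. The
marker direction is auto-chosen so AUC ≥ 0.5 (`"less"` markers count
*low* values as disease-enriched). Cut-off candidates are the midpoints
between adjacent distinct scores; the reported cut-off maximizes
Youden's J = sensitivity + specificity − 1, breaking exact ties toward
higher specificity — in a diagnostic setting the cheaper error is the
false negative that a follow-up test catches, not the false positive
that triggers intervention. Inference (95% CI, p vs 0.5) uses the
DeLong variance of paired placements. When that variance is exactly
zero (e.g. perfect separation) the CI collapses to a point and p is 0
(or 1 at AUC = 0.5); a bootstrap fallback was deliberately not used, as
it would make an otherwise deterministic result stochastic without
changing its interpretation.

Candidate combination defaults to the **directional exceedance count**:
each marker contributes 1 when the sample lies beyond its univariate
cut-off in its case-enriched direction. This is the same rule as the
k-of-n composite signature (prognostic default: 3 of 5), so the
diagnostic combination and the prognostic score share one mechanism. A
logistic-regression combination is available (`method = "logistic"`)
but documented as non-canonical. Degenerate (constant) markers have no
cut-off and contribute 0 to every sample — a combined score can
therefore never be perturbed by a dead antibody. In permutation nulls
the score's direction must be held fixed (`direction = "greater"`);
re-choosing the direction per permutation would bias the permuted AUC
above 0.5 by construction.

## Unsupervised views

Z scores use the sample-SD (n − 1) convention; zero-variance endpoints
are dropped with a warning since they carry no contrast. Two-way
clustering runs Ward's method (`ward.D2`) on Euclidean distances of the
standardized matrix for both samples and endpoints; merge heights are
verified against a naive Lance–Williams implementation. Tie-breaking
among equidistant merges follows `hclust`'s deterministic order, which
is platform-stable — the point of declaring a tie rule at all. PCA is
the eigen-decomposition of the covariance (not correlation) matrix of
column-centered data, computed via SVD; each loading's sign is fixed so
its largest-magnitude entry is positive, removing the sign ambiguity
that otherwise breaks reproducibility across BLAS builds. Missing cells
are rejected unless the caller explicitly opts into dropping incomplete
endpoints — silent imputation would change the geometry being
clustered.

## What the synthetic generator emulates — and what it does not

`generate_slide()` reproduces the assay's *structure*: triplicate
spots, two print concentrations with proportional mass loading, a
shared total-protein channel, a negative-control slide of identical
geometry, and multi-group cohorts with multiplicative per-(endpoint,
group) effects. Its noise model has three layers, all multiplicative
log-normal with unit mean:

* `noise_cv` — independent per-spot technical noise (default 0.1);
* `loading_cv` — a per-sample loading multiplier shared between the
  antibody and Sypro channels (default: equal to `noise_cv`), which
  total-protein normalization is designed to cancel;
* `biological_cv` — a per-(sample, endpoint) multiplier shared across
  replicates and concentrations (default 0), modeling inter-individual
  variability of true marker levels. This is the component that does
  not average away over technical replicates; recovery experiments for
  marker panels use 0.2, a mid-range value for serum protein markers.

Tying `loading_cv` to `noise_cv` by default makes a noiseless cohort
exactly deterministic, which the exact-recovery tests rely on: with all
CVs at 0, the full normalization chain returns the programmed
`baseline × effect` values bit-exactly, and group-mean ratios equal the
programmed effects.

The generator does **not** emulate spatial slide artifacts, antibody
cross-reactivity, saturation/nonlinearity of the detection chain, or
heavy-tailed outlier spots. Green tests therefore demonstrate that the
*procedures* are correct under a well-behaved assay model, not that
real serum-EV data will reach any particular AUC; effect sizes and CVs
in the defaults are plausible placeholders, not estimates of any
specific study's assay.

All randomness flows from one integer seed through `derive_seed()`
(a deterministic hash of seed + consumer tag), so every stage draws an
independent but reproducible stream and a rerun of `run_study()` with
the same configuration yields byte-identical outputs — verified by
hashing every written artifact.

## Problem sizes and degenerate inputs

The validation suite favors exhaustive small cases over sampled large
ones: ROC oracle equality is checked on *every* labeling of score sets
up to length 12 plus 1,000 random instances; calibration recovery uses
8-point × 3-replicate curves over 200 seeds per slope; LOD agreement
500 seeds × three k values; clustering oracles 200 random 8 × 5
matrices; panel recovery 100 cohorts of 12 vs 12 samples with 20
endpoints. These sizes make the whole suite run in a few minutes on a
single core while keeping every check at full strength.

Degenerate inputs are contracts, not afterthoughts: constant scores
yield AUC 0.5 with no cut-off; flat reference curves refuse inversion;
all-missing replicate sets propagate an explicit missing marker;
uncovered clinical cells return `"unclassified"`; and every rejection
names the offending record.

## Known limitations

* Inter-slide spatial normalization and batch correction are out of
  scope; the chain assumes slides are comparable after the
  total-protein step.
* The log-log calibration is linear only within the dilution range;
  four/five-parameter logistic models for saturating curves are not
  implemented.
* `classify_risk` implements one published stratification; it is not a
  general D'Amico calculator.
* Survival modeling (Cox, time-dependent ROC) is deliberately absent;
  recurrence is treated as a binary endpoint.
```{r session}
sessionInfo()
```
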