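---
title: "Quantifying intratumoral heterogeneity and sampling bias in RPPA studies"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying intratumoral heterogeneity and sampling bias in RPPA studies}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Reverse phase protein arrays (RPPA) measure the relative abundance of a
panel of signaling proteins — including phosphorylated (activated) forms —
across many tissue lysates at once. When such measurements feed prognostic
or predictive biomarkers, a single biopsy is implicitly assumed to
represent the whole tumor. `rppaHet` quantifies how safe that assumption
is: it measures how much protein expression varies *within* one tumor
(intratumoral heterogeneity) relative to variation *between* patients, and
it simulates the concrete consequence — differential-expression calls that
appear or vanish depending on which single sample of a tumor was assayed.

The package is organized around a cohort layout typical of multi-region
sampling studies in high-grade serous ovarian carcinoma: around a dozen
primary tumors sampled at 5–9 distinct locations each, a reference set of
normal fallopian-tube epithelium (from healthy individuals and from
uninvolved contralateral tubes of cancer patients, one sample per
individual), and a panel of 36 signaling proteins of which 15 are
phosphoproteins. The default `study_design()` encodes exactly this: 13
patients, sample counts (7×10, 6×3) summing to 88, 10 + 4 normals. The
true per-patient breakdown of such cohorts is rarely published; the fixed
sequence is a documented stand-in within the stated 5–9 range, and every
count is configurable.

## The generative model

`generate_study()` draws expression of protein $k$ in sample $j$ of tumor
patient $i$ as

$$ y_{kij} = \mu_k \; e^{\delta_k} \; e^{b_{ki}} \; e^{w_{kij}}, \qquad
   b_{ki} \sim N(0, \sigma_{b,k}^2), \quad w_{kij} \sim N(0, \sigma_{w,k}^2), $$

with $\delta_k$ a tumor-vs-normal natural-log fold change (zero except on
the configured differential subset). Normal-tissue individuals contribute
one sample each, $\mu_k e^{u_{ki}}$, with their own between-individual
component and no tumor effect — there is no within-individual replication
for normals, because reference tissue is rarely available in multiple
regions per person.

Noise is **lognormal (multiplicative)** by design: expression values are
non-negative intensity ratios, the analysis is CV-based, and under a
lognormal law the coefficient of variation is independent of the mean, so
one parameter per variance component targets the dispersion directly. The
identity $\sigma = \sqrt{\log(1 + \mathrm{CV}^2)}$ (exposed as
`cv_to_sigma()` / `sigma_to_cv()`, and tested as a bijection and by
Monte-Carlo) converts CV targets into log-scale standard deviations.

Default targets are the dispersions the package is designed to study:
within-tumor CV 0.25, between-patient CV 0.21, normal between-individual
CV 0.27 — all per protein, all overridable. The defaults are the study
conditions; they are not tuned per analysis.

### The spot-level layer

`generate_spot_data()` realizes each matrix cell as a serial dilution
(1, 1:2, 1:4, 1:8, 1:16) printed in duplicate plus two buffer blanks — 12
spots per (protein, sample) — with expected signal
$\text{background} + \text{value} \times d$, mean-one multiplicative
lognormal spot noise (`spot_cv`), and optional saturation clipping. Buffer
blanks are recorded with `dilution_fraction = 0`. A per-sample
total-protein signal (a stand-in for a Sypro Ruby whole-slide stain) is
emitted alongside; because such a stain aggregates signal over the entire
dilution series, its noise CV (`total_cv`) defaults to 0 and is kept
separate from single-spot noise. Two totals modes exist:
`total_reference = "sum"` (proportional to the sample's summed latent
expression — unequal loading) and `"constant"` (lysates adjusted to equal
protein concentration before printing). Only the constant mode makes
"quantify then normalize" an exact inverse of generation, which is how the
round-trip tests are posed.

## Quantification

`quantify_study()` turns spot tables into one value per (protein, sample):
mean-blank background subtraction clipped at zero, then a robust
serial-dilution estimate, then total-protein normalization
(`value × reference / total`, reference defaulting to the cohort median
total so results are invariant to global staining intensity).

The estimator is the **median of dilution-corrected signals**
($\text{signal}/d$) over valid spots — valid meaning not below the
detection floor and not above `saturation_threshold` (default 0.95) times
the array's maximum observed signal. This choice is parameter-light,
linear in the signals, robust to a clipped top dilution, and exact in the
noiseless limit (the dilution fractions are powers of two, so even the
floating-point round trip is bit-exact). Joint response-curve fitting
across an array (SuperCurve-style logistic models) is a richer alternative
and deliberately out of scope. Cells with fewer than `min_valid_spots`
usable spots are **missing, never zero**, with a machine-readable reason
(`"floor"`, `"saturation"`, `"too_few"`); missingness propagates through
every downstream statistic.

## Heterogeneity statistics

All dispersion measures are coefficients of variation in percent,
`cv() = 100 · sd / mean` with the $n-1$ standard deviation — the
small-sample choice appropriate for 5–9 samples per patient.

* `intratumoral_cvs()`: one CV per (protein, patient) over that patient's
  tumor samples; patients with fewer than two usable values are skipped
  and logged.
* `rms_average()`: per-protein pooling of the per-patient CVs by the
  root-mean-square, which weights heterogeneous patients upward and always
  dominates the arithmetic mean.
* `interpatient_cv()`: CV across patients of per-patient mean expression
  (for normals, across individuals' single values).
* `group_summary()`: means and ranges for all proteins, phosphoproteins,
  and non-phosphoproteins; empty groups are omitted, not zeroed.
* `friedman_cv_test()`: do proteins differ in heterogeneity? Blocks are
  patients, treatments are proteins, observations the per-(patient,
  protein) CVs — the only layout in which "compare CVs between proteins"
  is a blocked comparison across the cohort. Incomplete blocks are dropped
  listwise with a reported count; a fully tied design yields statistic 0
  and p = 1.
* `mann_whitney()`: two-sided; exact p from the null distribution of U
  when the pooled size is ≤ 16 with no ties, otherwise the normal
  approximation with tie and continuity correction; the method used is
  recorded in the result.
* `boxplot_stats()`: quartiles by linear interpolation between order
  statistics (the convention is fixed so results reproduce bit-for-bit),
  whiskers at the most extreme points within 1.5 × IQR.

No multiple-testing correction is applied by default, matching the
descriptive, per-protein reporting style of heterogeneity studies; users
can apply `p.adjust` to any result column.

## Clustering

`cluster_study()` follows the classic Cluster/TreeView recipe:
log~2~-transform, center each protein row at its median, compute sample
distances $1 - \rho_\text{Spearman}$ over pairwise-complete proteins
(midrank ties), and agglomerate with average linkage (UPGMA). Distances
are rank-based, hence invariant to any strictly increasing per-sample
transformation; UPGMA heights are monotone, so the dendrogram has no
inversions. Samples are sorted lexicographically before agglomeration so
equal-distance merges resolve identically on every run. The signed
$1-\rho$ (not $1-|\rho|$) keeps anti-correlated samples maximally distant.
Trees export to Newick via `ape` for external viewers.

`cocluster_score()` makes "samples from the same patient cluster
together" quantitative: cut the tree into $k$ flat clusters (default: the
number of patients) and report the fraction of same-patient pairs sharing
a cluster, plus a per-patient scattered flag. `per_tumor_means = TRUE`
instead clusters per-tumor mean profiles together with the individual
normal samples — the tumor-vs-normal separation view.

## The sampling-bias experiment

`run_sampling_bias_experiment()` compares two ways of calling
tumor-vs-normal differential expression with a Mann–Whitney test per
protein:

* **mean-based**: one summary per tumor patient (n = 13 summaries vs all
  normal values). Comparing summaries — not all 88 samples — against 14
  normals avoids pseudo-replicating patients.
* **single-sample**: one randomly selected sample per patient, repeated
  (default three times). When every patient has at least as many samples
  as repetitions, draws are made without reuse across repetitions, so the
  repeated analyses share no tumor data; a `reuse` mode covers smaller
  designs. Selections are fully seed-determined.

The per-patient summary is the **geometric mean** by default. This is a
deliberate design choice: expression is analyzed on the log scale
throughout the package, and the geometric mean is exactly the mean on that
scale. Under multiplicative noise the arithmetic mean of a patient's
samples acquires a Jensen offset of $e^{\sigma_w^2/2}$ relative to
single-sample normal values, which shifts the rank test away from its
nominal level precisely when within-tumor heterogeneity is large — the
regime this experiment exists to probe. The geometric summary keeps null
proteins at the nominal two-sided 5% level (verified in the acceptance
suite), while `patient_summary = "arithmetic"` remains available for
sensitivity analyses. Directions come from medians, consistent with the
rank-based test.

`classify_concordance()` assigns each protein to one category by
precedence — `all_four` (significant by mean and in every repetition),
`mean_only_strict` (significant by mean, missed by every single-sample
analysis), `singles_only`, `partial`, `none` — flags direction conflicts
among significant calls, and reports both readings of "missed in single
samples" (missed by all repetitions; missed by at least one). A packaged
fixture transcribing a published four-analysis comparison of the
36-protein panel (`load_table2_fixture()` / `table2_results()`) exercises
the classification layer on real reported p-values; its phosphoprotein
flags are curated rather than parsed from names, because prefix heuristics
misclassify proteins like p38 MAPK.

## What the synthetic generator does and does not emulate

It reproduces the features the statistics consume: hierarchical
multiplicative variance with realistic magnitudes, configurable
tumor-vs-normal effects, missing-value plumbing, and a spot-level layer
with background, noise and saturation. It does **not** emulate spatially
structured heterogeneity (clonal geography), protein–protein correlation
within samples, antibody cross-reactivity, array-to-array batch effects,
or non-lognormal outliers. Green tests therefore certify the pipeline's
correctness and calibration under the stated variance model — not that
real tumors satisfy that model.

## Numerical conventions and degenerate inputs

* CV requires ≥ 2 finite values and a positive mean; expression values are
  positive by construction.
* Missing is first-class everywhere: empty TSV cells read as `NA`,
  quantification emits `NA` with reasons, CVs use non-missing entries when
  ≥ 2 remain, Spearman pairs need ≥ 3 shared proteins (an error names the
  offending pair), Friedman deletes incomplete blocks listwise.
* Determinism: every stochastic entry point takes an integer seed; the
  random-draw order inside the generators is fixed and documented, so a
  seed pins output bit-for-bit across runs.
* Tie-breaking: agglomeration order is fixed by lexicographic sample ids;
  Mann–Whitney switches exact/approximate by an explicit, recorded rule.

## Problem sizes used by the test suite

The suite validates statistics against brute-force oracles (full
Mann–Whitney enumeration up to pooled n = 10, all 216 rank assignments of
the 3×3 Friedman design, naive $O(n^3)$ UPGMA), and calibrates the
pipeline by simulation at deliberately modest sizes chosen to give tight
Monte-Carlo error while keeping the default run fast: 20 seeds of the
13 × 7 cohort for variance recovery, 200 study replicates for the
power-ordering and type-I checks, 10 seeds per noise level for the
co-clustering trend, and $10^5$ draws for the lognormal CV identity.
`scripts/acceptance.R` reruns the headline quantities end-to-end from a
single command-line seed.

## Known limitations

Per-protein variance components are estimated descriptively (CVs), not by
mixed models — confidence intervals on CVs are out of scope. The
quantification layer assumes per-sample total-protein normalization; the
fixture-based concordance replay validates classification logic, not the
underlying p-values, which cannot be recomputed without the original
patient-level data.
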