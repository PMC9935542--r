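---
title: "Expression-ranked connectivity curves: models, choices, limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Expression-ranked connectivity curves: models, choices, limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(rankcurve)
```

## The analysis model

`rankcurve` quantifies the resemblance between two region-by-region
effect matrices — typically the allele-dose effect of a risk variant on
resting-state connectivity and a drug contrast from a crossover
pharmaco-fMRI study — as a function of regional marker-gene expression.

**First level.** For a T x R matrix of ROI time series, connectivity is
the Pearson correlation of each region pair, Fisher-z transformed:
`z = atanh(r)`. The transform stabilizes the variance (approximately
1/(T-3) for white noise) so that second-level linear models on z are
well behaved. No denoising happens here: the package consumes
post-preprocessing series, and its synthetic series need none.

**Second level.** The genetic effect matrix holds, per edge, the OLS
coefficient of the C-allele count (0/1/2, additive coding; a dominant
recoding {0}->0, {1,2}->1 is available for exploratory analyses), with
gender and haloperidol-equivalent dose as covariates of no interest.
Covariates enter unstandardized — the coefficient of interest is
invariant to that choice. The pharmacological matrices hold the mean
within-subject paired contrast built from post-pre session differences
(so session-constant offsets cancel), tested by the paired t with
df = n - 1. The phrase "the regression coefficients entered a one-sample
t-test" in common software pipelines is, under OLS, equivalent to the
coefficient's GLM t statistic, which is what `fit_edge_glm()` reports.

**Expression ranking.** Regions are ranked by the mean z-scored
expression of marker genes (defaults GRIN1, parvalbumin, SLC17A7; any
set, e.g. with GRIN2A substituted, runs unchanged). Aggregation is
donor-first: z-score each gene within each donor's samples, average
samples within region per donor, average regions across donors, then
re-standardize across regions. The donor-first order prevents donors
with more samples from dominating, and the within-donor z-score makes
the ranking exactly invariant to any affine rescaling of one donor's raw
intensities (microarray batch/sensitivity differences). The aggregation
order is a documented package choice; "averaged z-values" alone does not
pin it down. Ties in the combined score break by region label order;
regions with fewer than `min_samples` (default 1) samples are flagged
unsupported, ranked last, and excluded from curve analyses.

**The curve and its AUC.** With regions sorted by rank (1 = highest
expression), iteration k correlates the lower triangles of both effect
matrices restricted to the top (R - k + 1) regions, until three regions
remain: a full 106-region atlas gives 104 curve points and a full-size
edge vector of 5565 values. The AUC is the plain sum of the r values
(unit spacing). The trapezoid rule is available (`auc_rule =
"trapezoid"`); it differs only in halving the two endpoint weights, and
the sum is the default because the magnitudes it produces are the ones
conventionally reported for this statistic.

**Permutation inference.** Whole-brain edge vectors are heavily
interdependent, so no analytic null for the AUC is attempted. Instead
the genotype column is shuffled across patients — gender and dose stay
with their subjects, matching a null in which genotype is exchangeable
but the nuisance structure is real — and the per-edge GLM, the curve and
the AUC are recomputed per shuffle. The p-value uses the add-one
estimator `(1 + #beyond) / (1 + n_perm)` rather than a raw percentage;
it cannot return 0 and is the standard finite-sample-valid choice.
Directions are one-sided by hypothesis: greater for ketamine-positive
contrasts, less for midazolam > placebo. Across the three contrasts,
Benjamini-Hochberg is applied; the FDR variant is a package choice since
"FDR-corrected" alone does not name one.

**Network, seed and symptom analyses.** The set-level (functional
network connectivity) statistic is the GLM on the per-subject mean
Fisher-z over the between-set (or within-set) edges, with per-edge
post-hoc GLMs listed at uncorrected p < 0.05. This transparent scalar
form replaces the omnibus SVD-component F of some toolboxes, whose exact
construction is not reproducible from the literature; the scalar test is
exactly calibrated (its null behavior is part of the test suite) and its
effect equals the mean of the per-edge effects by linearity of OLS.
Data-driven networks come from average-linkage hierarchical clustering
on 1 - Pearson correlation between the rows of the group-mean
connectivity matrix (diagonal masked); linkage and distance are package
choices, k defaults to 10 and is configurable, and regions are
canonically sorted first so the result is order-invariant. Symptom
domains (Bern-scale language/affective/motor subcategory sums; items are
bipolar -1/0/+1 ratings) are tested by a multivariate GLM: Wilks Lambda
= det(E)/det(E+H) for the single-df allele hypothesis, converted by
Rao's exact relation F = ((1-L)/L) ((v_e - p + 1)/p) on (p, v_e - p + 1)
df. Degrees of freedom are always computed from first principles
(n - rank(X)); published df bookkeeping for such tables is often off by
one or two depending on the N entering each test, and the package does
not try to mimic any particular bookkeeping. Post-hoc partial
correlations residualize both variables on the covariates
(df = n - c - 2); discovery tests are two-sided, directed verification
re-tests one-sided.

## The synthetic-data generator

The generator emulates the statistical structure of all three inputs:

* **Cohort**: genotypes i.i.d. from Hardy-Weinberg proportions at a
  configurable C-allele frequency (default 0.277; the observed counts
  such a cohort produces match HWE closely, so no inbreeding parameter
  is modeled). Patient gender is Bernoulli(0.5) and dose
  Gamma(shape 2, scale 3) truncated at 30 mg/day with a 10%
  never-medicated fraction — placeholders for a split the source data do
  not report, used only as nuisance structure. The pharmaco arm is male,
  as in the emulated crossover study, with six sessions per subject.
* **Time series**: zero-mean multivariate normal draws whose correlation
  matrix is a constant-baseline matrix (off-diagonal 0.1) plus an
  additive perturbation confined to edges among the configured signal
  regions — `allele_count * allele_effect` for patients,
  `ket_effect`/`mdz_effect` for the pharmaco post sessions — projected
  to the nearest valid correlation matrix by eigenvalue clipping at 1e-6
  and diagonal renormalization. For small perturbations the projection
  keeps the planted effect approximately linear in allele count (the
  validation suite measures the residual bias of the recovered
  coefficient at about +4%, from the atanh curvature, against a <10%
  bound). Optional per-region `signal_weights` grade the
  perturbation as `delta * w_i * w_j`; a geometric decay across the
  ranked signal regions emulates effects whose magnitude tracks
  expression and produces the characteristic monotonically rising
  correlation curve, whereas a flat block makes the curve plateau once
  the submatrix is all-signal (both edge vectors become near-constant).
  No crossover order effects are simulated: paired post-pre differences
  cancel session-constant offsets by construction.
* **Expression**: six donors measure a shared latent regional score
  (plus gene-specific wobble) on donor-specific affine intensity scales
  with sampling noise, at jittered locations of labeled atlas voxels.
  The synthetic atlas is a small labeled grid with a NIfTI-convention
  affine, generated in code.
* **Symptoms**: the qualitative-language sum follows
  `a - b * allele + c * edge_connectivity + noise`, rounded and clipped
  to the subcategory's item range; all other subcategories are
  genotype-independent.

What the generator does **not** emulate: hemodynamic autocorrelation and
low-frequency structure of BOLD (white multivariate noise suffices to
exercise the statistics — but real effective df per correlation is lower
than T), scanner/site effects, registration error in the sample-to-atlas
mapping, missing genotypes, and probe-level microarray structure
(probe-to-gene aggregation is assumed done upstream). Passing tests
therefore certify the statistical machinery and its calibration under
exchangeability, not robustness to those real-data complications.

## Numerical choices

* Correlations are clipped to [-1 + 1e-7, 1 - 1e-7] before atanh, so a
  duplicated series yields a large finite z instead of infinity.
* The curve is computed by prefix cumulative sums over edges sorted by
  the larger rank position of their two regions: the edges of the top-s
  submatrix are exactly the first s(s-1)/2 in that order, so all R-2
  correlations come from one O(E) pass (R's long-double accumulators).
  The test suite pins this against a brute-force
  resort/reslice/recorrelate oracle at 1e-12.
* A submatrix whose edge vector is numerically constant (relative
  variance below 1e-12) records r = 0 with a warning flag instead of
  failing, so degenerate toy inputs cannot crash the curve.
* Exact fits (zero residual variance) floor p at the smallest positive
  double rather than returning 0.
* Wilks Lambda is clamped to at most 1 against roundoff; the single-df
  Rao conversion is exact, not an approximation.
* All simulation functions seed the RNG internally from the config seed
  (with small fixed offsets per stream), so any artifact is reproducible
  bit-exactly from one integer.

## Validation problem sizes

The test suite validates calibration and recovery at desk scale, chosen
to keep the whole suite within a few minutes while leaving the binomial
bounds meaningful: null calibration of the permutation test at R = 30
regions, 80 patients, 200 permutations and 200 simulated datasets
(type-I rate within [0.02, 0.09] at alpha = 0.05, p-values uniform by
KS); enrichment at R = 64 with the planted top-20 graded signal over 100
seeds; coefficient recovery at T = 500 and n = 146 over 50 seeds; and
network/symptom power and null suites at the sizes printed in the test
files. The acceptance script reruns one seeded instance of each.

## Known limitations

* The scalar FNC statistic is not the SVD-omnibus F some toolboxes
  print; degrees of freedom and F values are therefore not comparable
  with such outputs, though sign, calibration and FDR behavior are.
* The region table is a synthetic emulation of a 106-region
  Harvard-Oxford-style parcellation (real label volumes can be supplied
  via `read_atlas()`); analyses that depend on true anatomical geometry
  (e.g. voxelwise cluster inference) are out of scope, replaced by
  ROI-level seed profiles with BH correction across targets.
* Permutation inference assumes genotype exchangeability across patients
  given the covariates; confounding that violates it (e.g. ancestry
  stratification) is not modeled.
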