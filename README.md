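# rankcurve

Expression-ranked connectivity correlation curves for imaging genetics.

## The problem

A common strategy for validating a candidate disease variant is to ask
whether its imaging phenotype resembles a pharmacological model of the
implicated receptor system. For NMDA-receptor dysfunction in
schizophrenia this means comparing three datasets: resting-state fMRI
from genotyped patients (allele dose of a risk variant such as the
common intronic GRIN2A SNPs), a crossover pharmaco-fMRI study of the
NMDAR antagonist ketamine versus the GABA-A agonist midazolam (opposite
poles of excitation/inhibition), and postmortem whole-brain microarray
expression used to rank brain regions by marker genes of the implicated
microcircuit (GRIN1, parvalbumin, SLC17A7). `rankcurve` implements that
integrative analysis as a tested, reusable R pipeline, together with a
synthetic-data generator that reproduces the statistical structure of
all three inputs so every component can be validated end to end.

## The core statistic

For each subject and session, ROI time series on an R = 106 region
parcellation give a Fisher-z connectivity matrix,
z_ij = atanh(cor(x_i, x_j)). Second-level effect matrices are

* **genetic**: the per-edge OLS coefficient of the C-allele count
  (additive model, 0/1/2) with gender and haloperidol-equivalent dose as
  nuisance covariates;
* **pharmacological**: the mean within-subject paired contrast, e.g.
  ketamine > placebo = (ket post − ket pre) − (pla post − pla pre),
  ketamine > midazolam analogously.

Regions are ranked by their combined marker-gene expression (donor-wise
z-scores from the six-donor microarray set, aggregated per region and
re-standardized). The **correlation curve** is

r(s) = Pearson correlation of the lower triangles of both effect
matrices restricted to the top-s ranked regions, for s = R, R−1, …, 3,

obtained by iteratively removing the lowest-expressing region. Its
summary is the discrete AUC = Σ_s r(s). Because edges are strongly
interdependent, inference is by permutation of the genotype labels
(covariates stay with their subjects): the per-edge GLM, the full curve
and the AUC are recomputed for each of n_perm shuffles, and
p = (1 + #{null AUC beyond observed}) / (1 + n_perm), Benjamini-Hochberg
corrected over the pharmacological contrasts. Set-level (functional
network connectivity) tests, data-driven hierarchical clustering of
regions, ROI seed profiles, Wilks-lambda symptom-domain MANOVA and
partial-correlation coupling complete the pipeline.

## Worked example

```r
library(rankcurve)

summarize_genotypes(c(TT = 76, TC = 59, CC = 11))
#> Genotype summary (n = 146)
#>   C-allele frequency: 27.7%
#>                TT   TC  CC
#> observed     52.1 40.4 7.5
#> HWE expected 52.2 40.1 7.7
```

The C-allele frequency and the Hardy-Weinberg expected genotype
fractions (q², 2pq, p²) agree with the observed fractions to a fraction
of a percent — the cohort is in equilibrium.

A synthetic end-to-end run with a shared, expression-graded signal
planted in the top-ranked regions:

```r
tab <- default_region_table()
labs <- tab$name[1:40]
cfg <- sim_config(seed = 1, n_patients = 60, n_controls = 0, n_pharmaco = 28,
                  n_timepoints = 100, region_labels = labs,
                  signal_regions = labs[1:12],
                  signal_weights = exp(-0.15 * (0:11)),
                  allele_effect = 0.25, ket_effect = 0.2, mdz_effect = -0.08)
cs  <- simulate_cohort(cfg)
ts  <- simulate_timeseries(cs$cohort, cs$sessions, cfg)
pat <- cs$cohort$subject_id[cs$cohort$group == "patient"]
conn <- lapply(paste0(pat, ".rest"),
               function(k) compute_connectivity(ts$series[[k]], labs))
names(conn) <- pat
Y  <- stack_connectivity(conn)
X  <- make_design(cs$cohort, "allele")
phr <- cs$cohort$subject_id[cs$cohort$group == "pharmaco"]
km <- paired_contrast(connectivity_by_session(ts, phr),
                      contrast_spec("ket_gt_mdz"))
res <- permutation_test(Y, X, list(ket_gt_mdz = km),
                        setNames(seq_along(labs), labs),
                        n_perm = 999, seed = 2)$ket_gt_mdz
```

This prints (via the `sprintf` calls of your choice):

```
AUC(ket>mdz) = 24.50 over 38 curve points; permutation p = 0.0010
curve r at full size: 0.41 -> r at size 5: 0.86
```

The correlation between the genetic and the ketamine-vs-midazolam effect
matrices rises from 0.41 on the whole matrix to 0.86 once only the
highest-expressing regions remain — the planted enrichment — and the AUC
sits far outside the genotype-permutation null (p ≈ 0.001).

`run_pipeline(run_config(...), out_dir)` executes the whole chain
(simulate → expression profiles → connectivity → GLMs → curves and
permutation → network tests → symptom tests) and writes TSV/JSON outputs
plus a hashed manifest in `report.json`; `scripts/run_pipeline.R` is a
thin command-line wrapper around it.

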