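# sanmf: subgraph-augmented NMF phenotyping of ICU physiological time series

`sanmf` derives discrete patient phenotypes from the irregular, sparsely
sampled multivariate physiological measurements recorded during the first
72 hours of an ICU stay. It is written for clinical data scientists and
biostatisticians who want an unsupervised, trend-based alternative to
single-time-point severity scores when subtyping critical-illness cohorts
(the motivating application is sepsis), together with the validation and
profiling machinery needed to judge whether the subtypes mean anything.

## Method

For each of 34 candidate physiological variables (vitals and labs, from
heart rate to bilirubin), the package

1. removes records outside per-variable measurable ranges, aggregates the
   remainder into uniform 6-h (or 24-h) windows, linearly interpolates
   empty interior windows and extends the edges,
2. standardizes the interpolated values cohort-wide into z-scores and
   rounds them (half away from zero, clipped at ±4) into integer *levels*,
   giving each patient-variable a 12-node chain graph,
3. mines every variable's chain corpus for frequent *subgraphs* —
   contiguous level runs of 2–6 nodes contained in at least `min_support`
   chains — and builds a sparse patient × subgraph occurrence-count matrix,
   zeroing per patient any pattern contained in a larger pattern that the
   same patient also exhibits (subsumption removal),
4. factorizes the count matrix X ≈ W·H with W ≥ 0 (patients × k patient
   group coefficients) and H ≥ 0 (k × subgraphs trend group coefficients)
   by multiplicative Frobenius updates across seeded restarts; restart
   agreement gives a consensus matrix whose **cophenetic correlation**
   (with a distinctiveness tie-breaker) selects the time interval, support
   threshold and component count k, and each patient is assigned to
   argmax<sub>j</sub> W<sub>ij</sub>,
5. summarizes each trend group by its representative subgraphs (top-100 H
   coefficients or coefficient > 1), and validates the phenotypes with
   gradient-boosting models: membership recovery from representative
   counts, and 30-day mortality against mean 7-day SOFA and Elixhauser
   comorbidity-index benchmarks,
6. profiles the subgroups: demographics/outcome tables, 7-day SOFA
   trajectories with organ subscores, comorbidity incidence tables (10%
   maximum-subgroup filter), and Welch/chi-square hypothesis-test
   batteries.

Because the source data for the motivating study is access-restricted, the
package ships a first-class synthetic-cohort generator
(`make_paperlike_spec()` / `generate_cohort()`) that plants three latent
trend groups — mutually equidistant one-period trajectory shapes across
the panel — with group-linked mortality (17%/28%/10%), SOFA trajectories
and comorbidity prevalences, plus ground-truth labels for recovery
testing.

## Worked example

```r
library(sanmf)

co  <- generate_cohort(make_paperlike_spec(120, seed = 42))
pr  <- prep_stage(co$records, interval = 6)
mat <- assemble_matrix(pr$corpora, co$patients$patient_id, min_support = 5)
fit <- sanmf(mat, k = 3, n_runs = 20, seed = 1)
print(fit)
mclust::adjustedRandIndex(fit$assignment, co$truth[names(fit$assignment)])
```

```
Synthetic ICU cohort: 120 patients, 92643 records, 34 variables
Group sizes: 27 / 47 / 46
30-day mortality: 15.8%
Subgraph-augmented NMF phenotyping
  120 patients x 4941 subgraphs, k = 3
  cophenetic correlation: 1.000 (20 consensus runs)
  phenotype sizes: 27 / 47 / 46
[1] 1
```

The cohort generator planted groups of 27/47/46 patients; mining retained
4,941 of 6,716 frequent subgraphs after subsumption removal; the k = 3
consensus factorization is perfectly stable (cophenetic correlation 1.0)
and the argmax memberships recover the planted groups exactly (adjusted
Rand index 1). `summary(fit)` lists each trend group's top-coefficient
subgraphs — e.g. `bun:1,0,-1,-1,-1,-1`, a blood-urea-nitrogen run falling
from one SD above the cohort mean to one below across six 6-h windows.
Downstream, `select_representatives()`, `train_mortality_model()` /
`compare_benchmarks()` and `profile_subgroups()` reproduce the validation
and profiling stages, and `run_pipeline(pipeline_config(...))` drives the
whole sequence from one seeded configuration with a run manifest.

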