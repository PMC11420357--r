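# crtpheno

Topological phenogrouping and survival analysis for cardiac
resynchronization therapy (CRT) cohorts.

## What it does, and for whom

Registry cohorts of CRT recipients mix phenotypes that may respond very
differently to the defibrillator component of the device (CRT-D vs the
pacemaker-only CRT-P). `crtpheno` is aimed at biostatisticians and
cardiology researchers who want to split such a cohort into data-driven
*phenogroups* and compare device-associated survival within each group. It
implements, as tested and reusable R functions:

1. **Preprocessing** — discard features with ≥ 40% missing values, mean
   imputation, z-scoring.
2. **Patient similarity network (Mapper)** — normalized correlation
   distance *d(i,j) = 1 − r(x_i, x_j)* between patients' feature vectors;
   two classical multidimensional-scaling lenses; an equalized overlapping
   product cover (resolution 29 bins/lens, gain 1.6 by default);
   single-linkage clustering with the first-gap histogram cut inside each
   cover cell; nodes are patient clusters and edges connect nodes sharing
   at least one patient.
3. **Phenogrouping** — drop nodes disconnected from the main network
   (their exclusive patients are outliers), Louvain community
   autogrouping, then an iterative merge down to *k* groups (default 5):
   at each step the group with the most outbound edges per node is merged
   into the neighbour it shares the most edges with. Phenogroups may
   overlap in patients; the overlap is preserved.
4. **Survival layer** — Kaplan–Meier estimates with Greenwood variances,
   reverse-KM follow-up, yearly absolute risk reduction
   *ARR(t) = [(1 − S_P(t)) − (1 − S_D(t))] × 100* pp with the
   "significant iff 0 outside the 95% CI" rule, log-rank tests, and Cox
   models (Efron ties) under study-specific right-censoring (CRT-D
   upgrade, LVAD, heart transplantation censor the all-cause endpoint; a
   sensitivity composite endpoint counts LVAD/transplant as events).
5. **Group statistics** — baseline two-arm tables (t / Mann–Whitney,
   chi-square / Fisher by the usual gates) and pairwise phenogroup
   contrasts (Kolmogorov–Smirnov for continuous features).
6. **Synthetic cohorts** — a generator with latent phenogroups,
   group-conditional features, non-random device assignment, exponential
   proportional-hazards event times, administrative and informative
   censoring, and per-feature MCAR missingness, so the entire chain is
   testable without registry data.

## Worked example

Generate a benchmark cohort with five well-separated latent groups, run the
full pipeline, and compare recovered phenogroups to the latent truth:

```r
library(crtpheno)

cohort <- generate_cohort(separated_cohort_config(n_patients = 1000, seed = 1))
rep <- run_pipeline(run_config(output_dir = "run1", seed = 1,
                               mapper = mapper_config(resolution = 6)),
                    cohort = cohort)
rep$phenogroup_sizes
#> [1] 241 213 205 192 242
rep$n_outliers; rep$n_multi_label
#> [1] 0
#> [1] 87
lab <- primary_labels(rep$assignment)
idx <- match(names(lab), cohort$features$patient_ids)
mclust::adjustedRandIndex(lab, cohort$latent[idx])
#> [1] 0.855
```

The network kept all 1000 patients (no disconnected nodes), grouped them
into five phenogroups of 192–242 patients with 87 patients on group
boundaries carrying two labels, and the recovered partition agrees with the
latent one at an adjusted Rand index of 0.855.

On a registry-like cohort (25 clinical features, realistic missingness,
group-dependent device assignment and device effects), the survival layer
reproduces the standard analysis outputs:

```r
co <- generate_cohort(default_cohort_config(n_patients = 2603, seed = 1))
device_cox(co$survival)$multivariable
#> Cox PH fit: n = 2603, events = 2094
#>  term     coef    hr ci_lo ci_hi      se        p
#>  crtd -0.16190 0.851 0.780 0.927 0.04398 0.000232
#>   age  0.00406 1.004 0.999 1.009 0.00243 0.095275
#>   ...
```

The adjusted device hazard ratio of 0.85 reflects the mixture of
group-specific effects the generator was configured with (a CRT-D benefit
in two of the five groups). `arr_table()` turns the two arms' KM curves
into the yearly ARR table with its CI-based significance flags.

Pipeline artifacts (GraphML network with mortality and phenogroup node
attributes, assignment CSV, KM/ARR/Cox tables, JSON run report with stage
counts and their consistency checks) land in the configured output
directory.

## Documentation

The methods vignette (`vignettes/crtpheno-methods.Rmd`) documents the
model and its assumptions, every tunable parameter with its default and
rationale, what the synthetic generator does and does not emulate, the
numerical conventions (tie-breaks, degenerate inputs, quantile type), and
known limitations.
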