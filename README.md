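# dyntraj

Latent-class trajectory modeling and dynamic prediction for longitudinal
blood markers.

Routinely collected blood tests (hemoglobin, white cells, creatinine,
electrolytes, ...) are measured irregularly throughout a hospital stay, and
the *shape* of each marker's trajectory carries prognostic information. This
package is for biostatisticians and clinical researchers who want to turn
such trajectories into dynamic predictors of binary outcomes — in-hospital
mortality, presence of spinal cord injury after spine trauma, or injury
severity — without hand-rolling the intermediate machinery.

## What it implements

**Trajectory model.** Per marker, a finite mixture of latent-process models:
a monotone link `H(y; η)` maps the observed value to a latent Gaussian
scale, where conditional on class *g*

```
H(y_ij) = B(t_ij)' β_g + Z(t_ij)' b_i + ε_ij,   ε_ij ~ N(0, σ²),
b_i ~ N(0, D),   P(class = g) = π_g
```

with a polynomial or natural-spline time basis `B(t)`, optional
intercept/slope random effects `Z(t)` (LCGA when absent, GMM when present),
and linear, monotone quadratic I-spline, or beta-CDF link families. Fitting
is multi-start EM with closed-form mean and variance-component updates and a
numeric substep for link parameters; the observed-data likelihood includes
the link Jacobian `Σ log H'(y)`.

**Model selection.** A 900-specification exploratory grid (markers × classes
1–5 × 3 links × polynomial degrees 1–3), scored by BIC, entropy-penalized
ICL, and average posterior probability of assignment (APPA ≥ 0.7, class
size ≥ 20), then refined as GMMs on natural-spline bases.

**Dynamic prediction.** Posterior class probabilities recomputed from data
up to landmark cutoffs (days 1, 3, 7, 14, 21) feed a repeated elastic-net
harness: 25 stratified 80/20 holdouts, 5-fold CV over the fixed
`alpha`/`lambda` grids scored by Cohen's kappa, ROC-AUC and PR-AUC in-train
and out-of-train with 95% t-intervals, and coefficient-magnitude variable
importance normalized to 100.

**Associations.** ANOVA / Kruskal–Wallis and (Monte-Carlo) Fisher tests of
class membership against demographics, with Benjamini–Hochberg q-values.

**Synthetic cohorts.** A seeded generator of EHR-like laboratory event
tables with known latent classes, front-loaded irregular sampling,
non-Gaussian marginals via inverse links, injected zeros/outliers, and
class-linked outcomes — so the whole chain is testable without access to
protected data.

## Worked example

```r
library(dyntraj)

cohort <- simulate_cohort(cohort_config(rng_seed = 42))
prep   <- preprocess_labs(cohort$labs, top_k = 6)
sum(prep$inclusion$included)
#> [1] 492

head(prep$filter_report[, c("marker", "n_input", "n_zero_removed", "n_fence_removed")], 3)
#>       marker n_input n_zero_removed n_fence_removed
#> 1 creatinine    5513             42              32
#> 2    glucose    5488             70              37
#> 3 hemoglobin    5424             59              20

series <- series_from_labs(prep$events, "hemoglobin")
fit <- fit_trajectory_model(
  series,
  trajectory_spec("hemoglobin", 3, time_basis("polynomial", 2), "linear", "none"),
  n_starts = 2, seed = 1)
fit
#> Latent-class trajectory model: marker 'hemoglobin'
#>   classes: 3 | basis: polynomial degree 2 | link: linear | random effects: none
#>   logLik: -7541.307  params: 14  subjects: 492  converged: TRUE
#>   class proportions: 0.421, 0.39, 0.189

compute_criteria(fit)[, c("bic", "icl", "appa_min", "min_class_size")]
#>        bic      icl  appa_min min_class_size
#> 1 15169.39 15216.35 0.9709276             91

posterior_probabilities(series, fit, cutoff_day = 7)[1:3, ]
#>   subject_id cutoff_day    ppa_1    ppa_2    ppa_3 map_class
#> 1      S0001          7 1.00e+00 6.24e-09 1.30e-29         1
#> 2      S0002          7 1.00e+00 6.83e-11 1.08e-35         1
#> 3      S0003          7 4.25e-07 1.00e+00 3.30e-04         2
```

The three fitted classes split the cohort 42/39/19% with high assignment
certainty (minimum APPA 0.97, smallest class 91 subjects); by day 7 most
subjects are already confidently assigned, which is what makes truncated
PPAs usable as early predictors. From here, `build_feature_matrix()` +
`run_experiment()` (or the one-call `run_pipeline()`) produce per-cutoff
ROC-AUC/PR-AUC tables and variable-importance rankings; see the vignette
`vignettes/dynamic-blood-biomarkers.Rmd` for the full methodology.

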