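---
title: "Latent-class blood-marker trajectories as dynamic predictors"
author: "dyntraj"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Latent-class blood-marker trajectories as dynamic predictors}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dyntraj)
```

## The problem

Routinely collected blood tests — hemoglobin, white cells, creatinine,
electrolytes — are measured repeatedly and irregularly during a hospital
stay. In acute spinal cord injury (SCI) and spine trauma, the *shape* of a
marker's trajectory over the first weeks carries prognostic information that
a single admission value does not. `dyntraj` implements a complete analysis
chain for treating such trajectories as dynamic biomarkers:

1. curate long-format laboratory events (zero removal, quantile-fence
   outlier filtering, marker selection, window truncation);
2. fit finite-mixture trajectory models per marker, so each subject carries
   a posterior probability of membership (PPA) in each latent trajectory
   class;
3. recompute those posteriors using only data up to a landmark cutoff
   (days 1, 3, 7, 14, 21), emulating prediction as data accrue;
4. feed PPAs — optionally with within-window summary statistics and baseline
   covariates — to a repeatedly held-out elastic-net classifier of binary
   outcomes (in-hospital mortality; SCI presence; SCI severity);
5. test class–covariate associations with false-discovery control.

Because the motivating data live behind credentialed access, the package
ships a synthetic cohort generator with known latent structure; every stage
is validated end-to-end against that ground truth.

## The trajectory model

For marker value $y_{ij}$ of subject $i$ at day $t_{ij}$, a monotone link
$H(\cdot;\eta)$ maps the observed scale to a latent Gaussian process scale:

$$ H(y_{ij};\eta) = B(t_{ij})^\top \beta_g + Z(t_{ij})^\top b_i +
   \varepsilon_{ij}, \qquad \varepsilon_{ij} \sim N(0, \sigma^2), $$

conditional on latent class $g$, with prior class probabilities $\pi_g$
given by an intercept-only multinomial logit. $B(t)$ is either a raw
polynomial basis (degree 1–3, used in the exploratory stage) or an
intercept-plus-natural-cubic-spline basis (refinement stage). $Z(t)$ is the
random-effect design — absent for latent class growth analysis (LCGA),
intercept or intercept+slope for growth mixture models (GMM) — with
$b_i \sim N(0, D)$, $D$ shared across classes. The observed-data
log-likelihood adds the Jacobian $\sum_{ij}\log H'(y_{ij})$.

Three link families cover the marginal shapes seen in laboratory data:

* **linear** — the identity. A free affine link would be unidentifiable
  jointly with free class intercepts and a free residual variance, so the
  linear family estimates no link parameters and $\sigma^2$ is free.
* **I-spline** — $H(y) = \sum_k c_k^2 I_k(y)$ with quadratic I-splines on
  three interior knots at the 25/50/75% value quantiles. Squared
  coefficients enforce monotonicity; the intercept is pinned to 0 (class
  intercepts absorb location) and $\sigma^2 \equiv 1$ (the coefficients
  carry scale).
* **beta CDF** — values are rescaled into the open unit interval with a
  buffer of $10^{-3}$ of the value range, then
  $H(y) = (F_{\mathrm{Beta}}(y^*; a, b) - \mathrm{loc})/\mathrm{scale}$ with
  location pinned to 0 and $\sigma^2 \equiv 1$; shapes and scale are free.

Pinning location/scale between link and linear predictor follows the usual
latent-process-model convention; the alternative (free link location plus a
dropped class intercept) parameterizes the same model.

`n_parameters()` implements the counting convention used in the BIC penalty:
$(G-1)$ membership logits $+\,G(d+1)$ fixed effects $+\,q(q+1)/2$ covariance
terms $+\,1$ residual variance $+$ a nominal per-family link count (linear
2, I-spline 6, beta 4). Counting conventions for such models vary across
software; this one is fixed and documented rather than claimed universal.

### Estimation

`fit_trajectory_model()` maximizes the marginal likelihood by multi-start
coordinate ascent:

* **E-step** — class responsibilities from the current parameters.
* **$\pi$, $\beta$** — closed-form update of the membership probabilities
  and a responsibility-weighted generalized-least-squares update of the
  class mean coefficients (per-subject covariance
  $V_i = Z_i D Z_i^\top + \sigma^2 I$).
* **$D$, $\sigma^2$** — the standard mixed-model EM update from posterior
  random-effect moments; closed form, monotone, and automatically positive
  semi-definite. For nonlinear links $\sigma^2$ stays at 1.
* **link parameters** — Nelder-Mead on the marginal likelihood (3–5
  parameters), run every third iteration; invalid proposals (non-monotone
  link, overflowing covariance) score $-\infty$.

The first ten iterations hold variances and link fixed so classes can form
before the random-effect variance is free to absorb between-class spread —
without this burn-in, mixture fits can collapse into one class with inflated
$D$. The first start seeds class means by k-means on per-subject
least-squares coefficients; the remaining starts perturb randomly
(`n_starts = 5` by default, `tol = 1e-6` relative log-likelihood,
`max_iter = 500`). A class prior falling below $1/(10n)$ marks the start
collapsed rather than silently degenerate. Fitted classes are re-ordered by
descending MAP-assignment count (ties by latent level at day 0) so PPA
feature columns are stable across refits. All randomness is governed by the
`seed` argument; identical inputs reproduce identical fits.

Near-singular covariances receive one jitter of $10^{-8}\,\mathrm{tr}(V)/n$
on the diagonal; log/Cholesky parameterizations keep variances positive.

### Model selection

The exploratory grid (`enumerate_lcga_grid()`) crosses markers × classes
1–5 × three link families × polynomial degrees 1–3, all LCGA — 900
specifications for a 20-marker panel. Each converged fit is scored
(`compute_criteria()`) by

* $\mathrm{BIC} = -2\ell + k \log n$ ($n$ = subjects),
* $\mathrm{ICL} = \mathrm{BIC} + 2E$ with
  $E = -\sum_{i,g} p_{ig}\log p_{ig}$ (the entropy-penalized ICL form),
* per-class APPA (mean posterior among MAP-assignees) and the smallest
  MAP class size.

`select_shortlist()` drops models whose minimum APPA falls below 0.7 or
whose smallest class has fewer than 20 MAP-assigned subjects (a count, not
expected mass; scaled down via argument for small cohorts), ranks the rest
by ICL with BIC as tiebreak, and keeps everything within $\Delta = 6$ ICL of
the best — a "strong evidence" window on the BIC scale — ordering near-ties
by parsimony. ICL leads and BIC breaks ties; that is one consistent reading
of mixed BIC-first/ICL-first practice, applied uniformly. If nothing
survives the constraints the best-BIC model is retained with a prominent
warning. `refine_with_gmm()` then refits shortlisted specifications with a
natural-spline basis of matching degrees of freedom and intercept+slope
random effects, keeping the best-ICL converged refit per marker and falling
back (flagged) to the LCGA fit when no refit converges.

## Landmark features and dynamic prediction

`posterior_probabilities()` recomputes PPAs from observations at or before
the cutoff day; the link Jacobian cancels across classes, and an empty
window returns the model's prior — a subject contributes a row at every
cutoff regardless of sampling sparsity. `build_feature_matrix()` assembles,
per experiment and cutoff, one of three predictor sets: PPAs alone; plus
within-window mean, SD (n−1), min and max per marker on the raw value
scale; plus one-hot baseline covariates (age, gender, ethnicity, insurance;
age and gender only for the external severity experiment). All $G$ PPA
columns per marker are kept — the elastic net tolerates the sum-to-one
collinearity. Summary cells from empty windows stay missing here and are
median-imputed *inside* the experiment harness with training-split
parameters only, so no test information leaks into imputation.

`run_experiment()` repeats, 25 times: one stratified 80/20 split (derived
from `base_seed + repeat`, hence identical across cutoffs and feature sets);
per configuration a grid search over the fixed mixing grid
$\alpha \in \{0, 0.11, \dots, 1\}$ and penalty grid
$\lambda \in \{10^{-4}, 0.11, \dots, 1\}$ by stratified five-fold
cross-validation scored with Cohen's kappa at a 0.5 probability threshold;
ties prefer the larger $\lambda$, then the larger $\alpha$ (the sparser
model — a deliberate bias toward regularization given the small holdouts).
Features are standardized with training mean/SD (constant columns get SD 1)
so glmnet coefficients are on the standardized scale. ROC-AUC is the
Mann–Whitney statistic with half-credit for ties; PR-AUC is step-wise
precision–recall interpolation. Aggregation reports means with 95%
t-intervals ($t_{0.975,24}\,s/\sqrt{25}$). Variable importance rescales
absolute standardized coefficients so the per-repeat maximum is 100, then
averages over repeats, flagging features above 40. Splitting and folds are
stratified by outcome — with mortality prevalence near 8%, unstratified
5-fold CV frequently produces single-class folds at this scale.

## Class–covariate associations

`class_covariate_associations()` tests each marker's MAP class assignment
against demographics and stay characteristics: one-way ANOVA for continuous
covariates (identical to $t^2$ for two classes; Kruskal–Wallis available by
flag, as cohort-description tables often prefer it), Fisher's exact test for
categorical covariates with a seeded 2000-replicate Monte-Carlo p-value for
tables beyond 2×2. p-values are Benjamini–Hochberg adjusted; the default
family is per marker across covariates (the grid display reads marker-wise),
with a global-family option. Significance is declared at $q < 0.05$.

## The synthetic cohort generator

`simulate_cohort()` draws, per subject: group (SCI with fracture, SCI
without fracture, spine trauma; default sizes 120/60/420, mirroring a
roughly 4:1 control imbalance at quarter scale), demographics with ages
truncated at 15 years, a log-normal length of stay with group medians near
11/8/7 days, and per marker a true class from the marker's class
probabilities. Observation times follow a front-loaded per-day Poisson
process (expected count $\lambda e^{-\kappa d}$ on day $d$, uniform jitter
within the day) intersected with the stay and the 21-day window. Values are
generated on the latent scale — class mean curve plus random intercept/slope
plus Gaussian residual — and pushed through the link inverse, so beta-linked
markers have skewed, bounded marginals. Zeros and symmetric $\ge 5$-SD
outliers are injected at configurable rates to exercise the filters (zeros
regardless of plausibility, by design). Outcomes are Bernoulli with log-odds
linear in the true class indicators of the first three markers and in age.

The default outcome coefficients were calibrated once so that the
*true-class* oracle discrimination for mortality is in the high-0.8/low-0.9
ROC-AUC range at 7–12% prevalence — the operating point reported for
comparable real cohorts — because a generator whose classes barely move the
outcome would make the kappa-tuned elastic net degenerate at desk scale and
would misrepresent the data-generating situation the pipeline targets.
`simulate_external_cohort()` reuses the machinery for a 137-subject
all-SCI validation cohort with its own sampling intensity, an optional
additive latent mean shift, and severity labels for everyone; trajectory
models are always frozen before being applied to it. Ground truth (class
labels, generating configuration) is returned in a separate component that
analysis stages never read.

What the generator does *not* emulate: unit changes and LOINC mapping,
informative sampling (sicker patients sampled more), missingness mechanisms
beyond sparsity, inter-marker correlation beyond shared outcome linkage, and
admission/discharge processes beyond a death flag. Passing tests therefore
demonstrate correctness of the machinery and recoverability under the stated
generative model, not clinical performance on real EHR data.

## Numerical choices and degenerate inputs

* Quantile convention everywhere: linear interpolation between order
  statistics (R type 7).
* Fence filter: thresholds at the 20th/80th percentiles with multiplier 1.5,
  pooled per marker over subjects; bounds inclusive; a constant marker
  yields equal fences and retains everything.
* Day truncation: `day <= 21` inclusive, day 0 = admission.
* Tie-breaks: marker selection by name; MAP class by lowest index; grid
  selection by larger $\lambda$ then larger $\alpha$; class ordering by
  assignment count then day-0 level.
* Empty landmark windows: prior PPAs, missing summaries (then imputed).
* Degenerate outcomes (single class) are refused by the classifier stage
  with an explicit error.
* All stochastic steps (generation, starts, folds, splits, Monte-Carlo
  Fisher) take explicit seeds and restore the caller's RNG state.

## Problem sizes used in the checks

The shipped tests and the acceptance script run at desk scale, chosen as the
smallest sizes at which the statistical properties are stable: oracle
equivalence on ~100 tiny instances; parameter recovery on one 300-subject
three-class cohort (~5–15 observations per subject); selection consistency
over 10 replicate 240-subject cohorts with a compact linear grid; the
prediction harness on the default 600-subject cohort with three modeled
markers, 25 repeats and all five cutoffs; and a fully deterministic
end-to-end rerun on a two-marker cohort. The full 900-model grid is
enumerated and counted, not exhaustively fitted, in the checks.

## Known limitations

* $D$ is shared across classes; class-specific random-effect variances are
  out of scope.
* No covariates in the membership model and no joint multi-marker mixtures —
  models are univariate per marker.
* The I-spline link requires observed values inside the fitting range;
  genuinely new out-of-range values at prediction time error rather than
  extrapolate.
* Kappa at a fixed 0.5 threshold is a blunt tuning signal for rare outcomes;
  it is retained as the field-standard default the pipeline mirrors, and the
  tie-break toward stronger regularization makes the failure mode (a null
  model) explicit rather than subtle.
* EM with closed-form variance updates converges linearly; very flat
  likelihoods near $D \to 0$ can exhaust `max_iter` and surface as
  `converged = FALSE` with an LCGA fallback in the refinement stage — a
  boundary diagnostic, not silent failure.
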