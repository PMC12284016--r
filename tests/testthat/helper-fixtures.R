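# Shared fixtures, built once per test run and memoised. All fixtures are
# generated in code under fixed seeds; nothing is read from disk.

.fixture_cache <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (!exists(name, envir = .fixture_cache))
    assign(name, builder(), envir = .fixture_cache)
  get(name, envir = .fixture_cache)
}

# Two-marker panel without contamination: one well-separated linear marker,
# one beta-linked marker. Kept small so trajectory fits stay fast.
small_panel <- function(sep = 6) {
  b1 <- time_basis("polynomial", 1)
  list(
    marker_truth("mk_lin", 2, c(0.6, 0.4),
                 rbind(c(0, 0.05), c(sep, -0.05)),
                 b1, link_linear(), re_sd = c(0, 0), resid_sd = 1),
    marker_truth("mk_beta", 2, c(0.5, 0.5),
                 rbind(c(-0.8, 0.03), c(0.8, -0.03)),
                 b1, link_beta(2, 4, scale = 0.08, location = 0.5,
                               range = c(1, 20)),
                 re_sd = c(0.2, 0), resid_sd = 0.5))
}

small_cohort <- function(n = c(SCI_Fracture = 40, SCI_noFracture = 20,
                               Spine_Trauma = 90), seed = 42L, ...) {
  simulate_cohort(cohort_config(
    n_subjects = n, markers = small_panel(), rng_seed = seed, ...))
}

# Three-class linear-link cohort used by recovery and selection tests:
# class means separated by ~3 residual sd at day 0 with distinct slopes.
three_class_truth <- function(resid_sd = 1, re_sd = c(0, 0)) {
  marker_truth("tri", 3, c(0.45, 0.35, 0.20),
               rbind(c(0.0, 0.05, 0.000),
                     c(3.2, -0.35, 0.012),
                     c(-3.2, 0.20, -0.004)),
               time_basis("polynomial", 2), link_linear(),
               re_sd = re_sd, resid_sd = resid_sd)
}

# Longer stays and a steadier sampling process give 5-15 observations per
# subject, the design condition of the recovery experiments.
three_class_cohort <- function(n_total = 300, seed = 7L, resid_sd = 1,
                               re_sd = c(0, 0)) {
  simulate_cohort(cohort_config(
    n_subjects = c(SCI_Fracture = round(n_total / 3),
                   SCI_noFracture = round(n_total / 3),
                   Spine_Trauma = n_total - 2 * round(n_total / 3)),
    markers = list(three_class_truth(resid_sd, re_sd)),
    los_meanlog = c(SCI_Fracture = log(14), SCI_noFracture = log(14),
                    Spine_Trauma = log(14)),
    los_sdlog = c(SCI_Fracture = 0.3, SCI_noFracture = 0.3,
                  Spine_Trauma = 0.3),
    sampling = list(rate = 0.85, decay = 0.03),
    rng_seed = seed))
}

# Align true classes with a fitted model's subjects.
true_classes_for <- function(cohort, marker, subject_ids) {
  tc <- cohort$truth$true_class
  tc[[marker]][match(subject_ids, tc$subject_id)]
}

# Memoised heavy fixtures ----------------------------------------------------

# Default cohort + preprocessed labs (used by several files).
fx_default_cohort <- function() fixture("default_cohort", function() {
  coh <- simulate_cohort(cohort_config(rng_seed = 20260111L))
  prep <- preprocess_labs(coh$labs, top_k = 6)
  list(cohort = coh, prep = prep)
})

# Fitted 3-class LCGA on the three-class cohort (recovery fixture).
fx_three_class_fit <- function() fixture("three_class_fit", function() {
  coh <- three_class_cohort(n_total = 300, seed = 7L)
  series <- series_from_labs(coh$labs, "tri")
  spec <- trajectory_spec("tri", 3, time_basis("polynomial", 2),
                          "linear", "none")
  fit <- suppressWarnings(fit_trajectory_model(series, spec, n_starts = 3,
                                               seed = 1L))
  list(cohort = coh, series = series, fit = fit)
})

# Small experiment fixture: models + feature matrices + experiment run for
# the mortality outcome on the default small-scale cohort.
fx_experiment <- function() fixture("experiment", function() {
  dc <- fx_default_cohort()
  prep <- dc$prep
  subjects <- dc$cohort$subjects[
    dc$cohort$subjects$subject_id %in% unique(prep$events$subject_id), ]
  # link families matching the generative marginals: gaussian hemoglobin,
  # skewed (beta-linked) wbc and creatinine
  links <- c(hemoglobin = "linear", wbc = "beta", creatinine = "beta")
  models <- list()
  for (m in names(links)) {
    G <- dc$cohort$truth$config$markers[[
      which(vapply(dc$cohort$truth$config$markers, `[[`, character(1),
                   "marker_name") == m)]]$n_classes
    series <- series_from_labs(prep$events, m, subjects$subject_id)
    spec <- trajectory_spec(m, G, time_basis("polynomial", 2),
                            links[[m]], "none")
    models[[m]] <- suppressWarnings(
      fit_trajectory_model(series, spec, n_starts = 2, seed = 1L))
  }
  features <- list()
  for (fs in c("ppa", "ppa_sum")) {
    features[[fs]] <- list()
    for (cd in c(1, 3, 7, 14, 21))
      features[[fs]][[as.character(cd)]] <- build_feature_matrix(
        subjects, models, prep$events, "I", cd, fs)
  }
  cfg <- experiment_config("I", cutoffs = c(1, 3, 7, 14, 21),
                           feature_sets = "ppa", n_repeats = 25,
                           base_seed = 100L)
  res <- run_experiment(cfg, features)
  list(subjects = subjects, models = models, features = features,
       config = cfg, result = res, prep = prep, cohort = dc$cohort)
})

# Brute-force mixture log-likelihood: explicit covariance assembly, dense
# multivariate normal density and explicit mixture sum. Independent of the
# package's likelihood code path.
brute_force_loglik <- function(series, model) {
  spec <- model$spec
  q <- switch(spec$random_effects, none = 0L, intercept = 1L,
              intercept_slope = 2L)
  G <- spec$n_classes
  total <- 0
  for (s in series) {
    tr <- link_transform(s$values, model$link)
    B <- evaluate_basis(s$times, spec$basis)
    ni <- length(s$times)
    V <- diag(model$sigma2, ni)
    if (q > 0) {
      Z <- cbind(1, s$times)[, seq_len(q), drop = FALSE]
      V <- V + Z %*% model$D %*% t(Z)
    }
    lg <- vapply(seq_len(G), function(g) {
      r <- tr$h - drop(B %*% model$beta[g, ])
      -0.5 * (ni * log(2 * pi) + determinant(V)$modulus[1] +
                drop(t(r) %*% solve(V) %*% r))
    }, numeric(1))
    lw <- log(model$pi) + lg     # explicit mixture sum, max-factored
    m0 <- max(lw)
    total <- total + m0 + log(sum(exp(lw - m0))) + sum(tr$log_jacobian)
  }
  total
}

# Random tiny model + data instance for oracle equivalence tests.
random_small_instance <- function(seed, max_G = 2, re = c("none", "intercept",
                                                          "intercept_slope")) {
  set.seed(seed)
  G <- sample.int(max_G, 1)
  reff <- sample(re, 1)
  deg <- sample(1:2, 1)
  spec <- trajectory_spec("toy", G, time_basis("polynomial", deg),
                          "linear", reff)
  q <- switch(reff, none = 0L, intercept = 1L, intercept_slope = 2L)
  n_subj <- sample(2:5, 1)
  series <- lapply(seq_len(n_subj), function(i) {
    ni <- sample(1:4, 1)
    t <- sort(round(runif(ni, 0, 21), 2))
    list(subject_id = paste0("s", i), times = t,
         values = rnorm(ni, 5, 2))
  })
  D <- NULL
  if (q > 0) {
    A <- matrix(rnorm(q * q, sd = 0.4), q, q)
    D <- A %*% t(A) + diag(0.05, q)
  }
  pi <- as.numeric(stats::runif(G) + 0.2)
  pi <- pi / sum(pi)
  model <- list(spec = spec, link = link_linear(),
                pi = pi,
                beta = matrix(rnorm(G * (deg + 1), sd = 1), G, deg + 1),
                D = D, sigma2 = runif(1, 0.3, 2))
  list(series = series, model = model)
}
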