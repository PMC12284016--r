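#' Ground-truth description of one synthetic marker
#'
#' Defines the generative model for one laboratory marker: latent classes with
#' class-specific mean curves on the latent scale, subject-level random
#' effects, residual noise, a link whose inverse shapes the observed marginal
#' distribution, and contamination rates for the zero and outlier filters to
#' exercise.
#'
#' @param marker_name marker name.
#' @param n_classes number of latent classes (>= 1).
#' @param class_probs class membership probabilities, summing to 1.
#' @param mean_coeffs `n_classes x (degree + 1)` matrix of latent-scale mean
#'   coefficients, rows indexed by class.
#' @param basis a [time_basis()].
#' @param link a link object ([link_linear()], [link_beta()],
#'   [link_ispline()]); observed values are `link_inverse(latent)`.
#' @param re_sd random-effect standard deviations `c(intercept, slope per day)`.
#' @param resid_sd residual standard deviation on the latent scale (> 0).
#' @param outlier_rate,zero_rate contamination proportions in [0, 1].
#' @return object of class `marker_truth`.
#' @export
marker_truth <- function(marker_name, n_classes, class_probs, mean_coeffs,
                         basis, link, re_sd = c(0, 0), resid_sd,
                         outlier_rate = 0, zero_rate = 0) {
  mean_coeffs <- as.matrix(mean_coeffs)
  stopifnot(n_classes >= 1,
            length(class_probs) == n_classes,
            abs(sum(class_probs) - 1) <= 1e-12,
            nrow(mean_coeffs) == n_classes,
            ncol(mean_coeffs) == basis$degree + 1,
            all(re_sd >= 0), resid_sd > 0,
            outlier_rate >= 0, outlier_rate <= 1,
            zero_rate >= 0, zero_rate <= 1)
  structure(list(marker_name = marker_name, n_classes = as.integer(n_classes),
                 class_probs = as.numeric(class_probs),
                 mean_coeffs = mean_coeffs, basis = basis, link = link,
                 re_sd = as.numeric(re_sd), resid_sd = resid_sd,
                 outlier_rate = outlier_rate, zero_rate = zero_rate),
            class = "marker_truth")
}

#' Default synthetic marker panel
#'
#' Six markers loosely styled on common hematology/chemistry analytes, with
#' 2-3 latent classes each, quadratic latent trends over the 21-day window,
#' linear links for approximately Gaussian markers and beta-CDF links for
#' skewed ones. Small zero and outlier contamination rates are included so
#' the preprocessing filters have work to do.
#'
#' @param contamination logical; include zero/outlier contamination
#'   (default `TRUE`).
#' @return list of [marker_truth()] objects.
#' @export
default_marker_panel <- function(contamination = TRUE) {
  zr <- if (contamination) 0.01 else 0
  orate <- if (contamination) 0.005 else 0
  b2 <- time_basis("polynomial", 2)
  hb <- marker_truth(
    "hemoglobin", 3, c(0.45, 0.35, 0.20),
    rbind(c(13.5, -0.10, 0.002),     # high, slow decline
          c(12.5, -0.60, 0.022),     # rapid early drop, partial recovery
          c(9.0,  0.05, 0.000)),     # persistently low
    b2, link_linear(), re_sd = c(0.7, 0.03), resid_sd = 0.8,
    outlier_rate = orate, zero_rate = zr)
  wbc <- marker_truth(
    "wbc", 3, c(0.30, 0.50, 0.20),
    rbind(c(1.2, -0.16, 0.005),
          c(0.0,  0.02, 0.000),
          c(-1.0, 0.18, -0.006)),
    b2, link_beta(shape1 = 2, shape2 = 5, scale = 0.08, location = 0.5,
              range = c(2, 30)),
    re_sd = c(0.45, 0.02), resid_sd = 0.6,
    outlier_rate = orate, zero_rate = zr)
  cre <- marker_truth(
    "creatinine", 2, c(0.75, 0.25),
    rbind(c(-0.8, 0.01, 0.000),
          c(0.9, -0.08, 0.003)),
    b2, link_beta(shape1 = 1.5, shape2 = 6, scale = 0.08, location = 0.5,
              range = c(0.2, 8)),
    re_sd = c(0.4, 0.015), resid_sd = 0.55,
    outlier_rate = orate, zero_rate = zr)
  na <- marker_truth(
    "sodium", 2, c(0.65, 0.35),
    rbind(c(139, 0.05, -0.002),
          c(134, 0.30, -0.010)),
    b2, link_linear(), re_sd = c(1.8, 0.05), resid_sd = 2.2,
    outlier_rate = orate, zero_rate = zr)
  plt <- marker_truth(
    "platelets", 3, c(0.40, 0.40, 0.20),
    rbind(c(0.6, -0.02, 0.003),
          c(-0.3, 0.14, -0.003),
          c(-1.4, 0.04, 0.002)),
    b2, link_beta(shape1 = 3, shape2 = 4, scale = 0.08, location = 0.5,
              range = c(30, 700)),
    re_sd = c(0.4, 0.015), resid_sd = 0.5,
    outlier_rate = orate, zero_rate = zr)
  glu <- marker_truth(
    "glucose", 2, c(0.6, 0.4),
    rbind(c(-0.3, 0.00, 0.000),
          c(0.8, -0.10, 0.003)),
    b2, link_beta(shape1 = 2, shape2 = 6, scale = 0.08, location = 0.5,
              range = c(50, 400)),
    re_sd = c(0.35, 0.01), resid_sd = 0.5,
    outlier_rate = orate, zero_rate = zr)
  list(hb, wbc, cre, na, plt, glu)
}

#' Synthetic cohort configuration
#'
#' @param n_subjects named integer vector of group sizes, names among
#'   `SCI_Fracture`, `SCI_noFracture`, `Spine_Trauma`.
#' @param markers list of [marker_truth()] objects.
#' @param los_meanlog,los_sdlog per-group log-normal length-of-stay
#'   parameters (days); defaults give medians near 11/8/7 days.
#' @param sampling per-day observation process: expected labs per marker on
#'   day `d` is `rate * exp(-decay * d)`.
#' @param outcome_coefs list with elements `mortality` and `severity`, each a
#'   list with `intercept`, `age` (per decade above 60) and `class_effects`
#'   (named list: marker -> per-class log-odds contribution).
#' @param rng_seed integer seed; identical seeds give identical cohorts.
#' @return object of class `cohort_config`.
#' @export
cohort_config <- function(n_subjects = c(SCI_Fracture = 120,
                                         SCI_noFracture = 60,
                                         Spine_Trauma = 420),
                          markers = default_marker_panel(),
                          los_meanlog = c(SCI_Fracture = log(11),
                                          SCI_noFracture = log(8),
                                          Spine_Trauma = log(7)),
                          los_sdlog = c(SCI_Fracture = 0.55,
                                        SCI_noFracture = 0.55,
                                        Spine_Trauma = 0.60),
                          sampling = list(rate = 1.6, decay = 0.10),
                          outcome_coefs = default_outcome_coefs(markers),
                          rng_seed = 20260101L) {
  stopifnot(all(n_subjects >= 1), sampling$rate > 0,
            all(names(n_subjects) %in%
                  c("SCI_Fracture", "SCI_noFracture", "Spine_Trauma")))
  structure(list(n_subjects = n_subjects, markers = markers,
                 los_meanlog = los_meanlog, los_sdlog = los_sdlog,
                 sampling = sampling, outcome_coefs = outcome_coefs,
                 rng_seed = as.integer(rng_seed)),
            class = "cohort_config")
}

#' Default outcome coefficient vectors
#'
#' In-hospital mortality and motor-complete severity are Bernoulli with
#' log-odds linear in true class indicators of the first three markers and
#' in age. Intercepts are set so mortality prevalence lands near the 7-12%
#' range seen in trauma cohorts.
#'
#' @param markers marker panel (class counts are read from it).
#' @return list with `mortality` and `severity` coefficient lists.
#' @export
default_outcome_coefs <- function(markers = default_marker_panel()) {
  eff <- function(G, size) {
    # class 1 protective, last class at risk, linear in between
    if (G == 1) return(0)
    size * (seq_len(G) - (G + 1) / 2) / ((G - 1) / 2)
  }
  nm <- vapply(markers, `[[`, character(1), "marker_name")
  ce <- stats::setNames(vector("list", length(nm)), nm)
  for (i in seq_along(markers)) ce[[i]] <- rep(0, markers[[i]]$n_classes)
  sizes <- c(1.1, 0.9, 0.7)
  for (i in seq_len(min(3L, length(markers))))
    ce[[nm[i]]] <- eff(markers[[i]]$n_classes, sizes[i])
  list(mortality = list(intercept = -3.2, age = 0.45,
                        class_effects = lapply(ce, `*`, 2)),
       severity = list(intercept = -0.6, age = 0.15, class_effects = ce))
}

group_demographics <- function(group, n) {
  age_mean <- switch(group, SCI_Fracture = 55, SCI_noFracture = 57,
                     Spine_Trauma = 63)
  male_p <- switch(group, SCI_Fracture = 0.74, SCI_noFracture = 0.70,
                   Spine_Trauma = 0.56)
  age <- round(pmax(stats::rnorm(n, age_mean, 18), 15), 1)
  gender <- sample(c("M", "F"), n, TRUE, c(male_p, 1 - male_p))
  ethnicity <- sample(c("WHITE", "BLACK", "HISPANIC", "ASIAN", "OTHER"),
                      n, TRUE, c(0.80, 0.07, 0.05, 0.02, 0.06))
  insurance <- sample(c("Medicare", "Medicaid", "Other"),
                      n, TRUE, c(0.37, 0.09, 0.54))
  data.frame(age = age, gender = gender, ethnicity = ethnicity,
             insurance = insurance, stringsAsFactors = FALSE)
}

simulate_marker_events <- function(subjects, truth, true_class, sampling,
                                   mean_shift = 0) {
  rows <- vector("list", nrow(subjects))
  for (i in seq_len(nrow(subjects))) {
    horizon <- min(subjects$length_of_stay[i], 21 + 1e-6)
    days <- 0:floor(min(subjects$length_of_stay[i], 21))
    counts <- stats::rpois(length(days),
                           sampling$rate * exp(-sampling$decay * days))
    t <- rep(days, counts) + stats::runif(sum(counts))
    t <- sort(t[t <= horizon])
    if (!length(t)) { rows[[i]] <- NULL; next }
    g <- true_class[i]
    B <- evaluate_basis(t, truth$basis)
    b <- stats::rnorm(2) * truth$re_sd
    lat <- drop(B %*% truth$mean_coeffs[g, ]) + mean_shift +
      b[1] + b[2] * t + stats::rnorm(length(t), 0, truth$resid_sd)
    y <- link_inverse(lat, truth$link, truth$marker_name)
    rows[[i]] <- data.frame(subject_id = subjects$subject_id[i], day = t,
                            marker = truth$marker_name, value = y,
                            stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}

contaminate <- function(values, zero_rate, outlier_rate) {
  n <- length(values)
  if (n == 0) return(values)
  u <- stats::runif(n)
  m <- mean(values); s <- stats::sd(values)
  if (!is.finite(s) || s == 0) s <- max(abs(m), 1) * 0.1
  is_zero <- u < zero_rate
  is_out <- !is_zero & u < zero_rate + outlier_rate
  if (any(is_out)) {
    sign <- sample(c(-1, 1), sum(is_out), TRUE)
    values[is_out] <- m + sign * (5 + stats::rexp(sum(is_out))) * s
  }
  values[is_zero] <- 0
  values
}

#' Simulate a synthetic EHR-like cohort
#'
#' Generates a subject table, a long lab-event table, and a ground-truth
#' table. Per subject and marker, observation times follow a front-loaded
#' per-day Poisson process on \eqn{[0, LOS] \cap [0, 21]}; the latent value is
#' \eqn{\Lambda_i(t) = B(t)^\top \beta_g + b_{i0} + b_{i1} t} plus Gaussian
#' residual noise, and the observed value is the link inverse of the latent
#' value. Zeros and extreme outliers are then injected at the configured
#' rates. In-hospital death and motor-complete severity are Bernoulli with
#' log-odds linear in true class indicators and age. Identical seeds give
#' identical outputs.
#'
#' @param config a [cohort_config()].
#' @return list with elements `subjects` (one row per subject: id, group,
#'   demographics, length of stay, outcome flags), `labs` (long table:
#'   `subject_id`, `day`, `marker`, `value`) and `truth` (per-subject true
#'   class per marker plus the generating configuration). The truth component
#'   is for evaluation only and must not feed analysis stages.
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  old_seed <- get0(".Random.seed", globalenv(), ifnotfound = NULL)
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                         envir = globalenv()))
  set.seed(config$rng_seed)
  simulate_cohort_impl(config, mean_shift = 0, severity_all = FALSE,
                       id_prefix = "S")
}

simulate_cohort_impl <- function(config, mean_shift, severity_all, id_prefix) {
  groups <- rep(names(config$n_subjects), config$n_subjects)
  n <- length(groups)
  subjects <- data.frame(
    subject_id = sprintf("%s%04d", id_prefix, seq_len(n)),
    group = groups, stringsAsFactors = FALSE)
  demo <- do.call(rbind, lapply(names(config$n_subjects), function(g)
    group_demographics(g, config$n_subjects[[g]])))
  subjects <- cbind(subjects, demo)
  subjects$length_of_stay <- pmax(stats::rlnorm(
    n, config$los_meanlog[subjects$group], config$los_sdlog[subjects$group]),
    0.5)

  true_class <- data.frame(subject_id = subjects$subject_id,
                           stringsAsFactors = FALSE)
  labs <- vector("list", length(config$markers))
  for (k in seq_along(config$markers)) {
    mt <- config$markers[[k]]
    tc <- sample.int(mt$n_classes, n, TRUE, mt$class_probs)
    true_class[[mt$marker_name]] <- tc
    ev <- simulate_marker_events(subjects, mt, tc, config$sampling,
                                 mean_shift = mean_shift)
    if (!is.null(ev) && nrow(ev) > 0)
      ev$value <- contaminate(ev$value, mt$zero_rate, mt$outlier_rate)
    labs[[k]] <- ev
  }
  labs <- do.call(rbind, labs)
  rownames(labs) <- NULL

  lp_class <- function(coefs) {
    lp <- coefs$intercept + coefs$age * (subjects$age - 60) / 10
    for (m in names(coefs$class_effects))
      if (m %in% names(true_class))
        lp <- lp + coefs$class_effects[[m]][true_class[[m]]]
    lp
  }
  subjects$died_in_hospital <-
    stats::rbinom(n, 1, stats::plogis(lp_class(config$outcome_coefs$mortality))) == 1
  sev <- stats::rbinom(n, 1, stats::plogis(lp_class(config$outcome_coefs$severity))) == 1
  subjects$severity_motor_complete <- if (severity_all) sev else
    ifelse(subjects$group == "Spine_Trauma", NA, sev)

  list(subjects = subjects, labs = labs,
       truth = list(true_class = true_class, config = config))
}

#' Simulate an external validation cohort
#'
#' Same generative model as [simulate_cohort()] with an optional additive
#' shift on the latent class means and its own sampling intensity, emulating
#' a smaller prospective cohort (default 137 subjects, all with spinal cord
#' injury) on which severity labels are available for every subject.
#'
#' @param config a [cohort_config()]; defaults to 137 subjects split between
#'   the two SCI groups with a sparser sampling process.
#' @param shift list with `mean_shift` (additive latent-scale shift applied
#'   to all class means) and optionally `rate_multiplier` for the sampling
#'   intensity.
#' @return same structure as [simulate_cohort()]; `severity_motor_complete`
#'   is set for all subjects.
#' @export
simulate_external_cohort <- function(
    config = cohort_config(n_subjects = c(SCI_Fracture = 85,
                                          SCI_noFracture = 52),
                           sampling = list(rate = 1.0, decay = 0.08),
                           rng_seed = 20260102L),
    shift = list(mean_shift = 0, rate_multiplier = 1)) {
  stopifnot(inherits(config, "cohort_config"),
            all(is.finite(unlist(shift))))
  config$sampling$rate <- config$sampling$rate *
    (shift$rate_multiplier %||% 1)
  old_seed <- get0(".Random.seed", globalenv(), ifnotfound = NULL)
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                         envir = globalenv()))
  set.seed(config$rng_seed)
  simulate_cohort_impl(config, mean_shift = shift$mean_shift %||% 0,
                       severity_all = TRUE, id_prefix = "T")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a simulated cohort to plain-text files
#'
#' Writes `subjects.csv`, `labs.csv` and `truth.json` under `dir`. The truth
#' file holds the evaluation-only class labels and is never read by analysis
#' stages.
#'
#' @param cohort result of [simulate_cohort()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(cohort$subjects, file.path(dir, "subjects.csv"),
                   row.names = FALSE)
  utils::write.csv(cohort$labs, file.path(dir, "labs.csv"), row.names = FALSE)
  jsonlite::write_json(cohort$truth$true_class,
                       file.path(dir, "truth.json"), digits = NA)
  invisible(dir)
}
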