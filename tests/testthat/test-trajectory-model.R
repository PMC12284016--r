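test_that("parameter counting follows the stated convention", {
  s1 <- trajectory_spec("m", 3, time_basis("polynomial", 3), "linear", "none")
  expect_equal(n_parameters(s1), 17)  # 2 + 12 + 0 + 1 + 2
  s2 <- trajectory_spec("m", 2, time_basis("natural_spline", 3), "linear",
                        "intercept_slope")
  expect_equal(n_parameters(s2), 15)  # 1 + 8 + 3 + 1 + 2
  # adding one class adds (d+1) fixed effects + 1 membership logit
  for (lf in c("linear", "ispline", "beta")) {
    a <- trajectory_spec("m", 2, time_basis("polynomial", 2), lf, "none")
    b <- trajectory_spec("m", 3, time_basis("polynomial", 2), lf, "none")
    expect_equal(n_parameters(b) - n_parameters(a), 4)
  }
})

test_that("G=1 linear LCGA likelihood equals the iid normal closed form", {
  set.seed(4)
  series <- lapply(1:4, function(i) {
    t <- sort(runif(3, 0, 21))
    list(subject_id = i, times = t, values = rnorm(3, 5 + 0.2 * t, 1))
  })
  spec <- trajectory_spec("m", 1, time_basis("polynomial", 1), "linear",
                          "none")
  beta <- matrix(c(5, 0.2), 1)
  model <- list(spec = spec, link = link_linear(), pi = 1, beta = beta,
                D = NULL, sigma2 = 1.3)
  closed <- sum(vapply(series, function(s)
    sum(dnorm(s$values, 5 + 0.2 * s$times, sqrt(1.3), log = TRUE)),
    numeric(1)))
  expect_equal(marginal_loglik(series, model), closed, tolerance = 1e-12)
})

test_that("a two-class mixture with identical components degenerates to one class", {
  set.seed(5)
  series <- lapply(1:3, function(i)
    list(subject_id = i, times = c(1, 4, 9), values = rnorm(3, 6, 1)))
  spec1 <- trajectory_spec("m", 1, time_basis("polynomial", 1), "linear",
                           "none")
  spec2 <- trajectory_spec("m", 2, time_basis("polynomial", 1), "linear",
                           "none")
  beta <- c(6, -0.1)
  m1 <- list(spec = spec1, link = link_linear(), pi = 1,
             beta = matrix(beta, 1), D = NULL, sigma2 = 0.8)
  m2 <- list(spec = spec2, link = link_linear(), pi = c(0.5, 0.5),
             beta = rbind(beta, beta), D = NULL, sigma2 = 0.8)
  expect_equal(marginal_loglik(series, m2), marginal_loglik(series, m1))
})

test_that("marginal likelihood matches a brute-force dense-covariance oracle", {
  for (seed in 1:60) {
    inst <- random_small_instance(seed)
    expect_equal(marginal_loglik(inst$series, inst$model),
                 brute_force_loglik(inst$series, inst$model),
                 tolerance = 1e-8)
  }
})

test_that("random-intercept likelihood matches 1-D adaptive quadrature", {
  for (seed in 1:20) {
    set.seed(seed)
    ni <- sample(2:5, 1)
    t <- sort(runif(ni, 0, 21))
    y <- rnorm(ni, 3, 1.5)
    series <- list(list(subject_id = "s", times = t, values = y))
    spec <- trajectory_spec("m", 1, time_basis("polynomial", 1), "linear",
                            "intercept")
    beta <- matrix(c(rnorm(1, 3), rnorm(1, 0, 0.1)), 1)
    tau2 <- runif(1, 0.1, 1); s2 <- runif(1, 0.3, 1.5)
    model <- list(spec = spec, link = link_linear(), pi = 1, beta = beta,
                  D = matrix(tau2), sigma2 = s2)
    mu <- beta[1] + beta[2] * t
    logf <- function(bi) sum(dnorm(y, mu + bi, sqrt(s2), log = TRUE)) +
      dnorm(bi, 0, sqrt(tau2), log = TRUE)
    bhat <- tau2 * sum(y - mu) / (ni * tau2 + s2)  # posterior mode
    C <- logf(bhat)  # factor out the peak to avoid underflow
    integrand <- function(b) vapply(b, function(bi) exp(logf(bi) - C),
                                    numeric(1))
    quad <- C + log(integrate(integrand, -Inf, Inf, rel.tol = 1e-10)$value)
    expect_equal(marginal_loglik(series, model), quad, tolerance = 1e-6)
  }
})

test_that("noise-free single-class data recovers the basis coefficients", {
  b2 <- time_basis("polynomial", 2)
  mt <- marker_truth("pure", 1, 1, rbind(c(2, 0.3, -0.01)), b2,
                     link_linear(), re_sd = c(0, 0), resid_sd = 1e-8)
  coh <- simulate_cohort(cohort_config(
    n_subjects = c(Spine_Trauma = 30), markers = list(mt), rng_seed = 8L))
  series <- series_from_labs(coh$labs, "pure")
  spec <- trajectory_spec("pure", 1, b2, "linear", "none")
  fit <- suppressWarnings(fit_trajectory_model(series, spec, n_starts = 1,
                                               seed = 1))
  expect_lt(max(abs(fit$beta - c(2, 0.3, -0.01))), 1e-3)
})

test_that("well-separated two-class data is classified perfectly", {
  coh <- small_cohort(n = c(Spine_Trauma = 200), seed = 9L)
  series <- series_from_labs(coh$labs, "mk_lin")
  spec <- trajectory_spec("mk_lin", 2, time_basis("polynomial", 1),
                          "linear", "none")
  fit <- suppressWarnings(fit_trajectory_model(series, spec, n_starts = 3,
                                               seed = 2))
  tc <- true_classes_for(coh, "mk_lin", fit$subject_ids)
  skip_if_not_installed("mclust")
  expect_equal(mclust::adjustedRandIndex(max.col(fit$posterior), tc), 1.0)
})

test_that("posteriors are normalized, respect cutoffs, and fall back to the prior", {
  fx <- fx_three_class_fit()
  for (cd in c(1, 7, 21)) {
    pp <- posterior_probabilities(fx$series, fx$fit, cd)
    P <- as.matrix(pp[, c("ppa_1", "ppa_2", "ppa_3")])
    expect_true(all(abs(rowSums(P) - 1) < 1e-10))
    expect_true(all(pp$map_class == max.col(P, ties.method = "first")))
  }
  empty <- list(list(subject_id = "ghost", times = numeric(0),
                     values = numeric(0)))
  pp0 <- posterior_probabilities(empty, fx$fit, 7)
  expect_equal(as.numeric(pp0[1, c("ppa_1", "ppa_2", "ppa_3")]), fx$fit$pi)
})

test_that("single-class models give probability one at any cutoff", {
  series <- lapply(1:5, function(i)
    list(subject_id = i, times = c(1, 2), values = c(5, 6)))
  spec <- trajectory_spec("m", 1, time_basis("polynomial", 1), "linear",
                          "none")
  fit <- suppressWarnings(fit_trajectory_model(series, spec, n_starts = 1,
                                               seed = 1))
  pp <- posterior_probabilities(series, fit, 3)
  expect_equal(pp$ppa_1, rep(1, 5))
})

test_that("single-observation posterior matches the scalar Bayes rule", {
  spec <- trajectory_spec("m", 2, time_basis("polynomial", 1), "linear",
                          "none")
  model <- structure(list(
    spec = spec, link = link_linear(), pi = c(0.3, 0.7),
    beta = rbind(c(2, 0), c(6, 0)), D = NULL, sigma2 = 1,
    zeta = log(0.3 / 0.7), loglik = NA, n_params = n_parameters(spec),
    converged = TRUE, n_subjects = 2, class_counts = c(1, 1),
    posterior = NULL, subject_ids = "s"), class = "trajectory_fit")
  y0 <- 3.1
  series <- list(list(subject_id = "s", times = 0.5, values = y0))
  pp <- posterior_probabilities(series, model, 1)
  f1 <- 0.3 * dnorm(y0, 2, 1); f2 <- 0.7 * dnorm(y0, 6, 1)
  expect_equal(pp$ppa_1, f1 / (f1 + f2), tolerance = 1e-10)
})

test_that("affine rescaling shifts the refit linear log-likelihood by -n log a", {
  coh <- three_class_cohort(n_total = 120, seed = 15L)
  series <- series_from_labs(coh$labs, "tri")
  a <- 2.5
  series2 <- lapply(series, function(s) {
    s$values <- a * s$values + 3; s
  })
  spec <- trajectory_spec("tri", 2, time_basis("polynomial", 1), "linear",
                          "none")
  f1 <- suppressWarnings(fit_trajectory_model(series, spec, n_starts = 2,
                                              seed = 3))
  f2 <- suppressWarnings(fit_trajectory_model(series2, spec, n_starts = 2,
                                              seed = 3))
  n_obs <- sum(vapply(series, function(s) length(s$times), integer(1)))
  expect_equal(f2$loglik, f1$loglik - n_obs * log(a), tolerance = 1e-3)
})

test_that("fits are deterministic given data, spec and seed", {
  coh <- small_cohort(n = c(Spine_Trauma = 80), seed = 10L)
  series <- series_from_labs(coh$labs, "mk_lin")
  spec <- trajectory_spec("mk_lin", 2, time_basis("polynomial", 1),
                          "linear", "none")
  f1 <- suppressWarnings(fit_trajectory_model(series, spec, n_starts = 2,
                                              seed = 11))
  f2 <- suppressWarnings(fit_trajectory_model(series, spec, n_starts = 2,
                                              seed = 11))
  expect_identical(f1, f2)
})

test_that("classes are canonicalized by descending assignment count", {
  fx <- fx_three_class_fit()
  counts <- fx$fit$class_counts
  expect_true(all(diff(counts) <= 0))
  expect_equal(fx$fit$pi, exp(c(fx$fit$zeta, 0)) / sum(exp(c(fx$fit$zeta, 0))))
})

test_that("fitted models serialize to JSON and reproduce posteriors", {
  fx <- fx_three_class_fit()
  path <- tempfile(fileext = ".json")
  write_trajectory_fit(fx$fit, path)
  back <- read_trajectory_fit(path)
  pp1 <- posterior_probabilities(fx$series, fx$fit, 7)
  pp2 <- posterior_probabilities(fx$series, back, 7)
  expect_equal(pp2, pp1, tolerance = 1e-12)
  expect_equal(back$loglik, fx$fit$loglik)
})

test_that("mean maximum posterior is nondecreasing as data accrues", {
  fx <- fx_three_class_fit()
  conf <- vapply(c(1, 3, 7, 14, 21), function(cd) {
    pp <- posterior_probabilities(fx$series, fx$fit, cd)
    mean(apply(as.matrix(pp[, c("ppa_1", "ppa_2", "ppa_3")]), 1, max))
  }, numeric(1))
  expect_true(all(diff(conf) >= -0.01))
})
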