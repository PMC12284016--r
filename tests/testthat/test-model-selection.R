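test_that("grid enumeration is the full ordered Cartesian product", {
  g900 <- enumerate_lcga_grid(sprintf("m%02d", 1:20))
  expect_equal(nrow(g900), 900)
  g1 <- enumerate_lcga_grid("a", class_range = 1, links = "linear",
                            poly_degrees = 1)
  expect_equal(nrow(g1), 1)
  g270 <- enumerate_lcga_grid(sprintf("m%d", 1:6))
  expect_equal(nrow(g270), 270)
  # deterministic ordering: marker, classes, link, degree
  expect_equal(g270$marker[1:45], rep("m1", 45))
  expect_equal(g270$n_classes[1:9], rep(1, 9))
  expect_equal(g270$degree[1:3], 1:3)
  # arbitrary factor cardinalities multiply
  g <- enumerate_lcga_grid(c("a", "b"), class_range = 2:3,
                           links = c("linear", "beta"), poly_degrees = 2)
  expect_equal(nrow(g), 2 * 2 * 2 * 1)
})

fake_fit <- function(posterior, loglik = -100, n_params = 5) {
  G <- ncol(posterior)
  spec <- trajectory_spec("fake", G, time_basis("polynomial", 1), "linear",
                          "none")
  structure(list(spec = spec, link = link_linear(),
                 pi = rep(1 / G, G), beta = matrix(0, G, 2), D = NULL,
                 sigma2 = 1, loglik = loglik, n_params = n_params,
                 converged = TRUE, n_subjects = nrow(posterior),
                 class_counts = tabulate(max.col(posterior), G),
                 posterior = posterior, subject_ids = NULL),
            class = "trajectory_fit")
}

test_that("criteria reduce to the analytic values in degenerate cases", {
  # G = 1: entropy 0, ICL = BIC, APPA = 1
  c1 <- compute_criteria(fake_fit(matrix(1, 10, 1), loglik = -50,
                                  n_params = 4))
  expect_equal(c1$entropy, 0)
  expect_equal(c1$icl, c1$bic)
  expect_equal(attr(c1, "appa"), 1)
  expect_equal(c1$bic, -2 * -50 + 4 * log(10))
  # all posteriors 0.5 in a G = 2 fit: entropy n log 2, APPA 0.5
  n <- 8
  c2 <- compute_criteria(fake_fit(matrix(0.5, n, 2)))
  expect_equal(c2$entropy, n * log(2))
  expect_equal(c2$icl - c2$bic, 2 * n * log(2))
  expect_equal(attr(c2, "appa"), c(0.5, NA))  # ties MAP to class 1
})

test_that("well-separated classes give near-unit APPA and ICL >= BIC always", {
  coh <- small_cohort(n = c(Spine_Trauma = 150), seed = 45L)
  series <- series_from_labs(coh$labs, "mk_lin")  # classes 6 sd apart
  sep_fit <- suppressWarnings(fit_trajectory_model(
    series, trajectory_spec("mk_lin", 2, time_basis("polynomial", 1),
                            "linear", "none"), n_starts = 2, seed = 1))
  cr_sep <- compute_criteria(sep_fit)
  expect_gte(cr_sep$appa_min, 0.95)

  fx <- fx_three_class_fit()
  cr <- compute_criteria(fx$fit)
  expect_gte(cr$icl, cr$bic - 1e-9)
  expect_gte(cr$appa_min, 0.85)
  # BIC round-trips from the stored components
  expect_equal(cr$bic,
               -2 * fx$fit$loglik + fx$fit$n_params * log(fx$fit$n_subjects),
               tolerance = 1e-9)
})

test_that("shortlisting enforces constraints, parsimony and the fallback", {
  base <- data.frame(
    marker = "a", n_classes = c(1, 2, 3), link = "linear", degree = 1,
    logLik = c(-120, -100, -99), n_params = c(4, 7, 10),
    n_subjects = 100, bic = c(258.4, 232.2, 244.1), entropy = c(0, 2, 30),
    icl = c(258.4, 236.2, 304.1), appa_min = c(1, 0.9, 0.55),
    min_class_size = c(100, 40, 5), valid = TRUE,
    stringsAsFactors = FALSE)
  s <- select_shortlist(base, appa_min = 0.7, min_class_size = 20)
  # 3-class violates APPA and size; 2-class wins on ICL, 1-class outside delta
  expect_equal(s$shortlist$n_classes, 2)
  # identical criteria, different n_params: fewer parameters ranked first
  tie <- base[c(2, 2), ]; tie$n_params <- c(9, 7)
  tie$min_class_size <- 40
  s2 <- select_shortlist(tie)
  expect_equal(s2$shortlist$n_params[1], 7)
  # all rows violating constraints fall back to best BIC with a warning
  bad <- base; bad$appa_min <- 0.2
  expect_warning(s3 <- select_shortlist(bad), "falling back")
  expect_equal(s3$shortlist$n_classes, 2)  # best BIC row
})

test_that("single-model shortlists pass through trivially", {
  one <- data.frame(marker = "a", n_classes = 1, link = "linear", degree = 2,
                    logLik = -10, n_params = 5, n_subjects = 50, bic = 40,
                    entropy = 0, icl = 40, appa_min = 1, min_class_size = 50,
                    valid = TRUE, stringsAsFactors = FALSE)
  s <- select_shortlist(one)
  expect_equal(nrow(s$shortlist), 1)
})

test_that("GMM refinement beats LCGA when random effects exist and finds none when absent", {
  coh_re <- three_class_cohort(n_total = 150, seed = 21L,
                               re_sd = c(0.8, 0.05))
  series <- series_from_labs(coh_re$labs, "tri")
  lcga <- suppressWarnings(fit_trajectory_model(
    series, trajectory_spec("tri", 3, time_basis("polynomial", 2), "linear",
                            "none"), n_starts = 2, seed = 5))
  gmm <- suppressWarnings(fit_trajectory_model(
    series, trajectory_spec("tri", 3, time_basis("natural_spline", 2),
                            "linear", "intercept_slope"),
    n_starts = 2, max_iter = 300, seed = 5))
  expect_gt(gmm$loglik, lcga$loglik)  # nested-model property

  coh0 <- three_class_cohort(n_total = 150, seed = 22L, re_sd = c(0, 0))
  series0 <- series_from_labs(coh0$labs, "tri")
  gmm0 <- suppressWarnings(fit_trajectory_model(
    series0, trajectory_spec("tri", 3, time_basis("natural_spline", 2),
                             "linear", "intercept_slope"),
    n_starts = 2, max_iter = 300, seed = 5))
  expect_true(all(diag(gmm0$D) < 0.05 * gmm0$sigma2))
})

test_that("refine_with_gmm returns the best converged refit per marker", {
  coh <- three_class_cohort(n_total = 150, seed = 23L, re_sd = c(0.5, 0.02))
  grid <- enumerate_lcga_grid("tri", class_range = 2:3, links = "linear",
                              poly_degrees = 2)
  fitted <- fit_lcga_grid(coh$labs, grid, n_starts = 2, seed = 3)
  expect_equal(nrow(fitted$criteria), 2)
  sel <- select_shortlist(fitted$criteria, min_class_size = 10)
  ref <- refine_with_gmm(sel$shortlist, coh$labs, n_starts = 2,
                         max_iter = 300, seed = 3)
  expect_true("tri" %in% names(ref))
  expect_s3_class(ref$tri$fit, "trajectory_fit")
  expect_true(ref$tri$refined)
  expect_equal(ref$tri$fit$spec$basis$kind, "natural_spline")
})
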