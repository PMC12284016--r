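test_that("hyperparameter grids are the fixed published search space", {
  g <- default_grids()
  expect_length(g$alpha, 10)
  expect_equal(g$alpha[c(1, 10)], c(0, 1))
  expect_equal(g$lambda[1], 0.0001)
  expect_length(g$lambda, 10)
  expect_equal(length(g$alpha) * length(g$lambda), 100)
})

test_that("ROC-AUC matches trivial cases and the derived pair count", {
  expect_equal(roc_auc(c(0, 0, 1, 1), c(0, 0, 1, 1)), 1.0)
  expect_equal(roc_auc(rep(0.3, 6), c(0, 1, 0, 1, 0, 1)), 0.5)
  expect_equal(roc_auc(c(0.1, 0.4, 0.35, 0.8), c(0, 0, 1, 1)), 0.75)
  expect_error(roc_auc(1:3, c(1, 1, 1)), "both classes")
})

test_that("ROC-AUC equals exhaustive Mann-Whitney pair counting with ties", {
  pair_count_auc <- function(s, l) {
    pos <- s[l == 1]; neg <- s[l == 0]
    tot <- 0
    for (p in pos) for (q in neg)
      tot <- tot + (p > q) + 0.5 * (p == q)
    tot / (length(pos) * length(neg))
  }
  set.seed(6)
  for (rep in 1:200) {
    n <- sample(2:8, 1)
    l <- c(0, 1, sample(0:1, n - 2, TRUE))
    s <- sample(seq(0, 1, 0.25), n, TRUE)  # coarse grid forces ties
    expect_equal(roc_auc(s, l), pair_count_auc(s, l))
  }
})

test_that("ROC-AUC agrees with an established implementation", {
  skip_if_not_installed("pROC")
  set.seed(7)
  s <- rnorm(60); l <- rbinom(60, 1, 0.4)
  expect_equal(roc_auc(s, l),
               as.numeric(pROC::auc(pROC::roc(l, s, quiet = TRUE,
                                              direction = "<"))))
})

test_that("PR-AUC of a random scorer concentrates near prevalence", {
  set.seed(8)
  n <- 500
  l <- rbinom(n, 1, 0.3)
  s <- runif(n)
  expect_lt(abs(pr_auc(s, l) - mean(l)), 0.05)
  expect_equal(pr_auc(l, l), 1.0)  # perfect scores
})

test_that("kappa tuning solves separable data and stays near zero under the null", {
  set.seed(9)
  n <- 200
  x <- cbind(a = rnorm(n), b = rnorm(n))
  y <- as.integer(x[, 1] > 0)
  fit <- tune_and_fit(x, y, cv_folds = 5, seed = 1)
  expect_gte(max(fit$kappa_grid, na.rm = TRUE), 0.95)
  expect_gte(fit$cv_kappa, 0.95)

  n2 <- 500
  x2 <- matrix(rnorm(n2 * 4), n2, 4,
               dimnames = list(NULL, paste0("f", 1:4)))
  y2 <- sample(rep(0:1, each = n2 / 2))  # permuted labels: no signal
  fit2 <- tune_and_fit(x2, y2, cv_folds = 5, seed = 2)
  expect_lt(abs(fit2$cv_kappa), 0.1)
  expect_error(tune_and_fit(x2, rep(1, n2)), "single class")
})

test_that("near-unpenalized ridge matches the unpenalized logistic oracle", {
  set.seed(10)
  n <- 400
  x <- cbind(x1 = rnorm(n), x2 = rnorm(n))
  y <- rbinom(n, 1, plogis(0.5 + 0.8 * x[, 1] - 0.5 * x[, 2]))
  xs <- scale(x)
  enet <- glmnet::glmnet(xs, y, family = "binomial", alpha = 0,
                         lambda = c(1, 0.0001), standardize = FALSE)
  cf <- as.numeric(coef(enet, s = 0.0001))
  oracle <- coef(glm(y ~ xs, family = binomial()))
  expect_lt(max(abs(cf - as.numeric(oracle))), 1e-3)
})

test_that("repeat splits are stratified and reused across cutoffs and feature sets", {
  fx <- fx_experiment()
  res <- fx$result$results
  # every (repeat, cutoff) cell exists
  expect_equal(nrow(res), 25 * 5 * 4)
  # alpha/lambda stay inside the grids
  g <- default_grids()
  expect_true(all(res$alpha %in% g$alpha))
  expect_true(all(res$lambda %in% g$lambda))
  # reconstruct the split for one repeat twice: identical membership
  y <- fx$features$ppa[["1"]]$y
  mk_split <- function(seed) {
    set.seed(seed)
    dyntraj:::stratified_split(y, 0.8)
  }
  expect_identical(mk_split(fx$config$base_seed + 3),
                   mk_split(fx$config$base_seed + 3))
  s <- mk_split(fx$config$base_seed + 3)
  expect_equal(mean(y[s]), mean(y), tolerance = 0.02)
})

test_that("experiment reruns are byte-identical under the same base seed", {
  fx <- fx_experiment()
  cfg_small <- experiment_config("I", cutoffs = c(1, 21),
                                 feature_sets = "ppa", n_repeats = 3,
                                 base_seed = 100L)
  r1 <- run_experiment(cfg_small, fx$features)
  r2 <- run_experiment(cfg_small, fx$features)
  expect_identical(r1$results, r2$results)
  expect_identical(r1$importance, r2$importance)
})

test_that("in-train performance dominates out-of-train on average", {
  fx <- fx_experiment()
  s <- fx$result$summary
  roc <- s[s$metric == "roc_auc", ]
  for (cd in unique(roc$cutoff)) {
    intr <- roc$mean[roc$cutoff == cd & roc$split == "in_train"]
    outt <- roc$mean[roc$cutoff == cd & roc$split == "out_of_train"]
    expect_gte(intr, outt - 0.02)
  }
})

test_that("aggregation produces t-based confidence intervals around the mean", {
  fx <- fx_experiment()
  s <- fx$result$summary
  expect_true(all(s$ci_lower <= s$mean + 1e-12))
  expect_true(all(s$ci_upper >= s$mean - 1e-12))
  one <- s[1, ]
  vals <- fx$result$results$value[
    fx$result$results$cutoff == one$cutoff &
      fx$result$results$feature_set == one$feature_set &
      fx$result$results$split == one$split &
      fx$result$results$metric == one$metric]
  expect_equal(one$mean, mean(vals))
  expect_equal(one$ci_upper - one$mean,
               qt(0.975, 24) * sd(vals) / 5)
})

test_that("variable importance normalizes to 100 and handles degenerate cases", {
  vi <- variable_importance(list(c(a = 0, b = 2, c = 0)))
  expect_equal(vi$mean_importance[vi$feature == "b"], 100)
  expect_equal(sum(vi$mean_importance), 100)
  vi2 <- variable_importance(list(c(a = -3, b = 3)))
  expect_equal(vi2$mean_importance, c(100, 100))
  vi0 <- variable_importance(list(c(a = 0, b = 0)))
  expect_equal(vi0$mean_importance, c(0, 0))
})
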