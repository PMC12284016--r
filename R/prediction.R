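#' Elastic-net hyperparameter grids
#'
#' The fixed mixing (`alpha`) and regularization (`lambda`) grids searched by
#' the classification stage: ten alphas from ridge (0) to lasso (1) in steps
#' of 0.11, and ten lambdas with a near-unpenalized 1e-4 anchor.
#'
#' @return list with numeric vectors `alpha` and `lambda`.
#' @export
default_grids <- function() {
  list(alpha = c(0.00, 0.11, 0.22, 0.33, 0.44, 0.55, 0.66, 0.77, 0.88, 1.00),
       lambda = c(0.0001, 0.11, 0.22, 0.33, 0.44, 0.55, 0.66, 0.77, 0.88,
                  1.00))
}

## Cohen's kappa for binary predictions at a fixed threshold.
kappa_stat <- function(pred, obs) {
  po <- mean(pred == obs)
  pe <- mean(pred) * mean(obs) + mean(1 - pred) * mean(1 - obs)
  if (pe >= 1) return(0)
  (po - pe) / (1 - pe)
}

## Stratified fold assignment: shuffles within each class, then deals folds
## round-robin so every fold keeps both classes whenever the minority class
## has >= k members.
stratified_folds <- function(y, k) {
  fold <- integer(length(y))
  for (cl in unique(y)) {
    idx <- sample(which(y == cl))
    fold[idx] <- rep_len(seq_len(k), length(idx))
  }
  fold
}

## Stratified train/test split preserving outcome prevalence.
stratified_split <- function(y, train_frac) {
  train <- logical(length(y))
  for (cl in unique(y)) {
    idx <- which(y == cl)
    n_tr <- max(1L, round(train_frac * length(idx)))
    train[sample(idx)[seq_len(min(n_tr, length(idx) - 1L))]] <- TRUE
  }
  train
}

#' ROC-AUC by the Mann-Whitney statistic
#'
#' Probability that a random positive outscores a random negative, with
#' half-credit for ties (midranks). Errors if only one class is present.
#'
#' @param scores numeric scores (higher = more positive).
#' @param labels 0/1 labels.
#' @return AUC in [0, 1].
#' @export
roc_auc <- function(scores, labels) {
  labels <- as.integer(labels)
  n1 <- sum(labels == 1); n0 <- sum(labels == 0)
  if (n1 == 0 || n0 == 0) stop("both classes required for ROC-AUC")
  r <- rank(scores)
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' PR-AUC by step-wise interpolation
#'
#' Area under the precision-recall curve computed by summing
#' `precision * delta-recall` over score thresholds, processing tied scores
#' as one block. For an uninformative scorer this concentrates near the
#' outcome prevalence.
#'
#' @inheritParams roc_auc
#' @return PR-AUC in [0, 1].
#' @export
pr_auc <- function(scores, labels) {
  labels <- as.integer(labels)
  P <- sum(labels == 1)
  if (P == 0 || all(labels == 1)) stop("both classes required for PR-AUC")
  o <- order(scores, decreasing = TRUE)
  s <- scores[o]; l <- labels[o]
  grp <- cumsum(!duplicated(s))
  tp <- cumsum(l); fp <- cumsum(1 - l)
  last <- !duplicated(grp, fromLast = TRUE)  # block boundaries
  tp <- tp[last]; fp <- fp[last]
  prec <- tp / (tp + fp)
  rec <- tp / P
  sum(diff(c(0, rec)) * prec)
}

#' Tune and fit a penalized logistic model
#'
#' Standardizes features with training mean/sd (constant columns get sd 1),
#' then grid-searches the elastic-net mixing and penalty parameters by
#' stratified k-fold cross-validation, scoring each pair with Cohen's kappa
#' at a 0.5 probability threshold. Ties prefer the larger lambda, then the
#' larger alpha (the sparser model). The winning pair is refit on the full
#' training set.
#'
#' @param x numeric feature matrix (no missing values).
#' @param y 0/1 outcome.
#' @param grids from [default_grids()].
#' @param cv_folds number of folds.
#' @param seed integer seed for fold assignment.
#' @return object of class `dyntraj_enet`: the glmnet fit plus the selected
#'   `alpha`, `lambda`, mean `cv_kappa`, the kappa grid, and the
#'   standardization `center`/`scale` used.
#' @export
tune_and_fit <- function(x, y, grids = default_grids(), cv_folds = 5,
                         seed = 1L) {
  y <- as.integer(y)
  if (length(unique(y)) < 2) stop("training outcome has a single class")
  ctr <- colMeans(x)
  scl <- apply(x, 2, stats::sd)
  scl[scl == 0 | !is.finite(scl)] <- 1
  xs <- scale(x, center = ctr, scale = scl)
  old_seed <- get0(".Random.seed", globalenv(), ifnotfound = NULL)
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                         envir = globalenv()))
  set.seed(seed)
  fold <- stratified_folds(y, cv_folds)
  lam <- sort(grids$lambda, decreasing = TRUE)
  kap <- array(NA_real_, c(length(grids$alpha), length(lam), cv_folds),
               dimnames = list(alpha = grids$alpha, lambda = lam, NULL))
  for (a in seq_along(grids$alpha)) {
    for (f in seq_len(cv_folds)) {
      tr <- fold != f
      if (length(unique(y[tr])) < 2 || length(unique(y[!tr])) < 2) next
      fit <- glmnet::glmnet(xs[tr, , drop = FALSE], y[tr],
                            family = "binomial", alpha = grids$alpha[a],
                            lambda = lam, standardize = FALSE)
      pr <- stats::predict(fit, xs[!tr, , drop = FALSE], s = lam,
                           type = "response")
      kap[a, , f] <- apply(pr >= 0.5, 2, kappa_stat, obs = y[!tr])
    }
  }
  mean_kap <- apply(kap, c(1, 2), mean, na.rm = TRUE)
  # best kappa; ties -> larger lambda, then larger alpha
  cand <- which(mean_kap >= max(mean_kap, na.rm = TRUE) - 1e-12,
                arr.ind = TRUE)
  cand <- cand[order(-lam[cand[, 2]], -grids$alpha[cand[, 1]]), ,
               drop = FALSE]
  a_best <- cand[1, 1]; l_best <- cand[1, 2]
  final <- glmnet::glmnet(xs, y, family = "binomial",
                          alpha = grids$alpha[a_best], lambda = lam,
                          standardize = FALSE)
  structure(list(fit = final, alpha = grids$alpha[a_best],
                 lambda = lam[l_best], cv_kappa = mean_kap[a_best, l_best],
                 kappa_grid = mean_kap, center = ctr, scale = scl),
            class = "dyntraj_enet")
}

#' Predicted probabilities from a tuned elastic-net model
#'
#' @param object a `dyntraj_enet`.
#' @param x feature matrix on the original (unstandardized) scale.
#' @param ... unused.
#' @return numeric vector of event probabilities.
#' @export
predict.dyntraj_enet <- function(object, x, ...) {
  xs <- scale(x, center = object$center, scale = object$scale)
  drop(stats::predict(object$fit, xs, s = object$lambda, type = "response"))
}

#' Standardized coefficients of a tuned elastic-net model
#'
#' @param object a `dyntraj_enet`.
#' @param ... unused.
#' @return named vector of coefficients on the standardized feature scale
#'   (intercept excluded).
#' @export
coef.dyntraj_enet <- function(object, ...) {
  cf <- stats::coef(object$fit, s = object$lambda)
  stats::setNames(as.numeric(cf)[-1], rownames(cf)[-1])
}

#' Configuration for a repeated dynamic-prediction experiment
#'
#' @param experiment `"I"`, `"II"` or `"III"`.
#' @param cutoffs landmark days.
#' @param feature_sets predictor sets to evaluate.
#' @param n_repeats number of repeated holdouts.
#' @param split training fraction.
#' @param cv_folds folds for hyperparameter tuning.
#' @param grids from [default_grids()].
#' @param base_seed repeat `r` uses seed `base_seed + r`, identical across
#'   cutoffs and feature sets so splits are comparable.
#' @return list of class `experiment_config`.
#' @export
experiment_config <- function(experiment = "I", cutoffs = c(1, 3, 7, 14, 21),
                              feature_sets = c("ppa", "ppa_sum",
                                               "ppa_sum_bl"),
                              n_repeats = 25, split = 0.8, cv_folds = 5,
                              grids = default_grids(), base_seed = 1L) {
  structure(list(experiment = experiment, cutoffs = cutoffs,
                 feature_sets = feature_sets, n_repeats = n_repeats,
                 split = split, cv_folds = cv_folds, grids = grids,
                 base_seed = as.integer(base_seed)),
            class = "experiment_config")
}

#' Run a repeated elastic-net dynamic-prediction experiment
#'
#' For each repeat: one stratified 80/20 split (derived from
#' `base_seed + repeat`, hence identical across cutoffs and feature sets),
#' median imputation learned on the training split, kappa-tuned elastic net,
#' and ROC-AUC / PR-AUC both in-train and out-of-train. Results are
#' aggregated as means with 95% t-based confidence intervals over repeats,
#' and standardized-coefficient variable importances are averaged per
#' (cutoff, feature set).
#'
#' @param config an [experiment_config()].
#' @param feature_matrices nested list `feature_matrices[[set]][[as.character(cutoff)]]`
#'   of [build_feature_matrix()] outputs sharing one cohort.
#' @return object of class `experiment_result`: `results` (long data frame:
#'   cutoff, feature_set, repeat, split, metric, value), `summary` (mean and
#'   CI per cutoff/set/split/metric), `importance` (per cutoff/set: feature,
#'   mean_importance, flag > 40), `config`.
#' @export
run_experiment <- function(config, feature_matrices) {
  stopifnot(inherits(config, "experiment_config"))
  y_ref <- NULL
  for (fs in config$feature_sets)
    for (cd in as.character(config$cutoffs)) {
      fm <- feature_matrices[[fs]][[cd]]
      if (is.null(fm)) stop("missing feature matrix for set '", fs,
                            "', cutoff ", cd)
      if (is.null(y_ref)) y_ref <- fm$y
      if (!identical(fm$y, y_ref))
        stop("feature matrices disagree on the outcome vector")
    }
  rows <- list(); imp <- list()
  for (r in seq_len(config$n_repeats)) {
    seed_r <- config$base_seed + r
    old_seed <- get0(".Random.seed", globalenv(), ifnotfound = NULL)
    set.seed(seed_r)
    train <- stratified_split(y_ref, config$split)
    if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                   envir = globalenv())
    for (fs in config$feature_sets) {
      for (cd in as.character(config$cutoffs)) {
        fm <- feature_matrices[[fs]][[cd]]
        med <- impute_fit(fm$x[train, , drop = FALSE])
        xtr <- impute_apply(fm$x[train, , drop = FALSE], med)
        xte <- impute_apply(fm$x[!train, , drop = FALSE], med)
        mod <- tune_and_fit(xtr, fm$y[train], config$grids,
                            config$cv_folds, seed = seed_r)
        p_tr <- predict(mod, xtr)
        p_te <- predict(mod, xte)
        rows[[length(rows) + 1]] <- data.frame(
          cutoff = as.numeric(cd), feature_set = fs, repeat_id = r,
          split = rep(c("in_train", "out_of_train"), each = 2),
          metric = rep(c("roc_auc", "pr_auc"), 2),
          value = c(roc_auc(p_tr, fm$y[train]), pr_auc(p_tr, fm$y[train]),
                    roc_auc(p_te, fm$y[!train]), pr_auc(p_te, fm$y[!train])),
          alpha = mod$alpha, lambda = mod$lambda, cv_kappa = mod$cv_kappa,
          stringsAsFactors = FALSE)
        imp[[paste(fs, cd, r, sep = "|")]] <- coef(mod)
      }
    }
  }
  results <- do.call(rbind, rows)
  summary <- aggregate_results(results, config$n_repeats)
  importance <- summarize_importance(imp, config)
  structure(list(results = results, summary = summary,
                 importance = importance, config = config),
            class = "experiment_result")
}

aggregate_results <- function(results, n_repeats) {
  agg <- stats::aggregate(value ~ cutoff + feature_set + split + metric,
                          data = results, FUN = mean)
  names(agg)[names(agg) == "value"] <- "mean"
  sdv <- stats::aggregate(value ~ cutoff + feature_set + split + metric,
                          data = results, FUN = stats::sd)
  agg$sd <- sdv$value
  half <- if (n_repeats > 1)
    stats::qt(0.975, n_repeats - 1) * agg$sd / sqrt(n_repeats) else 0
  agg$ci_lower <- agg$mean - half
  agg$ci_upper <- agg$mean + half
  agg
}

#' Coefficient-magnitude variable importance
#'
#' Per repeat, importance is the absolute standardized coefficient rescaled
#' so the largest equals 100 (an all-zero coefficient vector stays all-zero);
#' scores are then averaged over repeats and features with mean importance
#' above 40 are flagged.
#'
#' @param coef_list list of named coefficient vectors, one per repeat.
#' @return data frame with `feature`, `mean_importance`, `important`
#'   (mean > 40), sorted by decreasing importance.
#' @export
variable_importance <- function(coef_list) {
  stopifnot(length(coef_list) >= 1)
  scores <- vapply(coef_list, function(cf) {
    a <- abs(cf)
    if (max(a) > 0) a / max(a) * 100 else a
  }, numeric(length(coef_list[[1]])))
  mi <- rowMeans(scores)
  out <- data.frame(feature = names(coef_list[[1]]), mean_importance = mi,
                    important = mi > 40, stringsAsFactors = FALSE)
  out <- out[order(-out$mean_importance), , drop = FALSE]
  rownames(out) <- NULL
  out
}

summarize_importance <- function(imp, config) {
  out <- list()
  for (fs in config$feature_sets) {
    for (cd in as.character(config$cutoffs)) {
      keys <- paste(fs, cd, seq_len(config$n_repeats), sep = "|")
      tab <- variable_importance(imp[keys])
      tab$feature_set <- fs
      tab$cutoff <- as.numeric(cd)
      out[[paste(fs, cd)]] <- tab
    }
  }
  do.call(rbind, out)
}
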