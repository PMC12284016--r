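#' Within-window summary statistics for one series
#'
#' Mean, sample standard deviation (n-1 denominator), minimum and maximum of
#' the observations at or before the cutoff day. An empty window yields all
#' four as `NA`; a single observation yields `sd = NA`.
#'
#' @param times,values one subject's observation days and values.
#' @param cutoff_day landmark day.
#' @return named numeric vector `(mean, sd, min, max, n_obs)`.
#' @export
window_summary <- function(times, values, cutoff_day) {
  v <- values[times <= cutoff_day]
  n <- length(v)
  if (n == 0)
    return(c(mean = NA_real_, sd = NA_real_, min = NA_real_, max = NA_real_,
             n_obs = 0))
  c(mean = mean(v), sd = if (n > 1) stats::sd(v) else NA_real_,
    min = min(v), max = max(v), n_obs = n)
}

#' Outcome labels per experiment
#'
#' Experiment I: in-hospital mortality; Experiment II: presence of SCI
#' (either SCI group) versus spine trauma without SCI; Experiment III: motor
#' complete (AIS A or B) versus motor incomplete (AIS C, D or E) severity.
#'
#' @param subjects subject table.
#' @param experiment `"I"`, `"II"` or `"III"`.
#' @return integer 0/1 vector aligned with `subjects`; in Experiment III
#'   subjects without a severity label get `NA` (callers drop them with a
#'   warning).
#' @export
label_outcome <- function(subjects, experiment = c("I", "II", "III")) {
  experiment <- match.arg(experiment)
  switch(experiment,
         I = as.integer(subjects$died_in_hospital),
         II = as.integer(subjects$group %in% c("SCI_Fracture",
                                               "SCI_noFracture")),
         III = as.integer(subjects$severity_motor_complete))
}

#' Assemble a predictor matrix for one experiment and cutoff
#'
#' Builds the subjects-by-features matrix for a landmark cutoff out of three
#' blocks: posterior class-membership probabilities (PPA) per marker from the
#' frozen trajectory models, within-window summary statistics per marker, and
#' one-hot-encoded baseline covariates (Experiment III uses age and gender
#' only). Subjects absent from the labs keep prior PPAs and missing
#' summaries. Missing numeric entries are left as `NA` here and imputed with
#' training-split medians inside the experiment harness, so no test
#' information leaks into imputation.
#'
#' @param subjects subject table (experiment cohort).
#' @param models named list of `trajectory_fit` objects (one per marker).
#' @param labs curated long lab table.
#' @param experiment `"I"`, `"II"` or `"III"`.
#' @param cutoff_day landmark day in {1, 3, 7, 14, 21}.
#' @param feature_set `"ppa"`, `"ppa_sum"` or `"ppa_sum_bl"`.
#' @return object of class `feature_matrix`: list with `x` (numeric matrix,
#'   possibly containing `NA` in summary columns), `y` (0/1 outcome),
#'   `subject_id`, `experiment`, `cutoff_day`, `feature_set`.
#' @export
build_feature_matrix <- function(subjects, models, labs,
                                 experiment = c("I", "II", "III"),
                                 cutoff_day,
                                 feature_set = c("ppa", "ppa_sum",
                                                 "ppa_sum_bl")) {
  experiment <- match.arg(experiment)
  feature_set <- match.arg(feature_set)
  stopifnot(cutoff_day %in% c(1, 3, 7, 14, 21))
  y <- label_outcome(subjects, experiment)
  if (anyNA(y)) {
    warning(sum(is.na(y)), " subjects without a severity label dropped")
    subjects <- subjects[!is.na(y), , drop = FALSE]
    y <- y[!is.na(y)]
  }
  ids <- subjects$subject_id
  blocks <- list()
  for (m in names(models)) {
    series <- series_from_labs(labs, m, subjects = ids)
    pp <- posterior_probabilities(series, models[[m]], cutoff_day)
    G <- models[[m]]$spec$n_classes
    ppa <- as.matrix(pp[, paste0("ppa_", seq_len(G)), drop = FALSE])
    colnames(ppa) <- paste0(m, "_ppa", seq_len(G))
    blocks[[paste0(m, "_ppa")]] <- ppa
    if (feature_set %in% c("ppa_sum", "ppa_sum_bl")) {
      sm <- t(vapply(series, function(s)
        window_summary(s$times, s$values, cutoff_day)[1:4], numeric(4)))
      colnames(sm) <- paste0(m, "_", c("mean", "sd", "min", "max"))
      blocks[[paste0(m, "_sum")]] <- sm
    }
  }
  if (feature_set == "ppa_sum_bl") {
    bl <- list(age = subjects$age,
               gender_M = as.numeric(subjects$gender == "M"))
    if (experiment != "III") {
      for (v in c("ethnicity", "insurance")) {
        f <- factor(subjects[[v]])
        oh <- stats::model.matrix(~ f - 1)
        colnames(oh) <- paste0(v, "_", levels(f))
        bl[[v]] <- oh
      }
    }
    blocks$baseline <- do.call(cbind, bl)
  }
  x <- do.call(cbind, blocks)
  rownames(x) <- ids
  structure(list(x = x, y = y, subject_id = ids, experiment = experiment,
                 cutoff_day = cutoff_day, feature_set = feature_set),
            class = "feature_matrix")
}

#' Learn and apply median imputation
#'
#' `impute_fit()` records per-column medians on the training rows (columns
#' that are entirely missing get 0); `impute_apply()` fills missing entries
#' with those medians. Keeping the two steps separate guarantees imputation
#' parameters come from the training split only.
#'
#' @param x numeric matrix.
#' @return `impute_fit()`: named numeric vector of medians; `impute_apply()`:
#'   the completed matrix.
#' @export
impute_fit <- function(x) {
  med <- apply(x, 2, stats::median, na.rm = TRUE)
  med[!is.finite(med)] <- 0
  med
}

#' @rdname impute_fit
#' @param params medians from `impute_fit()`.
#' @export
impute_apply <- function(x, params) {
  for (j in seq_len(ncol(x))) {
    miss <- is.na(x[, j])
    if (any(miss)) x[miss, j] <- params[[j]]
  }
  x
}

#' Map AIS grades to the motor-complete outcome
#'
#' AIS A and B are motor complete (1); C, D and E are motor incomplete (0).
#'
#' @param ais character vector of AIS grades.
#' @return integer 0/1 vector (`NA` for unknown grades).
#' @export
ais_motor_complete <- function(ais) {
  out <- ifelse(ais %in% c("A", "B"), 1L,
                ifelse(ais %in% c("C", "D", "E"), 0L, NA_integer_))
  as.integer(out)
}
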