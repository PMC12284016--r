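#' End-to-end dynamic-biomarker pipeline
#'
#' Runs the full chain on a (simulated or supplied) cohort: laboratory
#' preprocessing, exploratory LCGA grid fitting, constrained ICL/BIC/APPA
#' shortlist selection, GMM refinement, landmark feature assembly, and the
#' repeated elastic-net experiment. All randomness derives from `seed`, so a
#' rerun with the same inputs reproduces identical result tables.
#'
#' @param cohort list with `subjects` and `labs` (e.g. from
#'   [simulate_cohort()]).
#' @param grid LCGA candidate grid; defaults to a compact grid (classes 1-4,
#'   linear link, degrees 1-2) over the preprocessed markers. Pass an
#'   [enumerate_lcga_grid()] result for the full search.
#' @param experiment experiment id for the prediction stage.
#' @param cutoffs landmark days.
#' @param feature_sets predictor sets.
#' @param n_repeats repeated holdouts.
#' @param top_k markers retained by preprocessing.
#' @param min_class_size class-size constraint, scaled to the cohort.
#' @param seed base seed for fitting and the experiment harness.
#' @param fit_args list of extra arguments to [fit_trajectory_model()]
#'   (e.g. `n_starts`, `max_iter`).
#' @return list with `prep`, `criteria`, `shortlist`, `models` (refined fit
#'   per marker), `features`, `experiment` (an `experiment_result`).
#' @export
run_pipeline <- function(cohort, grid = NULL, experiment = "I",
                         cutoffs = c(1, 3, 7, 14, 21),
                         feature_sets = c("ppa", "ppa_sum", "ppa_sum_bl"),
                         n_repeats = 25, top_k = 20, min_class_size = 20,
                         seed = 1L, fit_args = list()) {
  prep <- preprocess_labs(cohort$labs, top_k = top_k)
  subjects <- cohort$subjects[
    cohort$subjects$subject_id %in% unique(prep$events$subject_id), ,
    drop = FALSE]
  if (is.null(grid))
    grid <- enumerate_lcga_grid(prep$markers, class_range = 1:4,
                                links = "linear", poly_degrees = 1:2)
  fitted <- do.call(fit_lcga_grid,
                    c(list(labs = prep$events, grid = grid,
                           subjects = subjects$subject_id, seed = seed),
                      fit_args))
  sel <- select_shortlist(fitted$criteria, min_class_size = min_class_size)
  refined <- do.call(refine_with_gmm,
                     c(list(shortlist = sel$shortlist, labs = prep$events,
                            subjects = subjects$subject_id, seed = seed),
                       fit_args))
  models <- lapply(refined, `[[`, "fit")
  features <- list()
  for (fs in feature_sets) {
    features[[fs]] <- list()
    for (cd in cutoffs)
      features[[fs]][[as.character(cd)]] <- build_feature_matrix(
        subjects, models, prep$events, experiment, cd, fs)
  }
  cfg <- experiment_config(experiment, cutoffs, feature_sets,
                           n_repeats = n_repeats, base_seed = seed)
  exp_res <- run_experiment(cfg, features)
  list(prep = prep, criteria = fitted$criteria, shortlist = sel$shortlist,
       models = models, features = features, experiment = exp_res)
}
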