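#' Enumerate the exploratory LCGA candidate grid
#'
#' Full Cartesian product of markers, class counts, link families and
#' polynomial degrees, all without random effects, in deterministic order
#' (marker, classes, link, degree). With 20 markers, classes 1-5, three link
#' families and degrees 1-3 this yields 900 candidate specifications.
#'
#' @param markers character vector of marker names.
#' @param class_range integer vector of class counts.
#' @param links character vector of link families.
#' @param poly_degrees integer vector of polynomial degrees.
#' @return data frame of class `lcga_grid` with columns `marker`,
#'   `n_classes`, `link`, `degree`; use [grid_spec()] to materialize a row.
#' @export
enumerate_lcga_grid <- function(markers, class_range = 1:5,
                                links = c("linear", "ispline", "beta"),
                                poly_degrees = 1:3) {
  stopifnot(length(markers) > 0)
  g <- expand.grid(degree = sort(poly_degrees), link = links,
                   n_classes = sort(class_range), marker = markers,
                   KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  g <- g[, c("marker", "n_classes", "link", "degree")]
  rownames(g) <- NULL
  class(g) <- c("lcga_grid", "data.frame")
  g
}

#' Materialize one grid row as a trajectory specification
#'
#' @param grid an [enumerate_lcga_grid()] result.
#' @param i row index.
#' @param boundary time boundary in days.
#' @return a [trajectory_spec()] (LCGA: no random effects).
#' @export
grid_spec <- function(grid, i, boundary = c(0, 21)) {
  trajectory_spec(grid$marker[i], grid$n_classes[i],
                  time_basis("polynomial", grid$degree[i],
                             boundary = boundary),
                  link_family = grid$link[i], random_effects = "none")
}

#' Model-selection criteria for a fitted trajectory model
#'
#' BIC \eqn{= -2\ell + k \log n}; entropy of the posterior responsibilities
#' \eqn{E = -\sum_i\sum_g p_{ig} \log p_{ig}} (with \eqn{0\log 0 = 0}); ICL
#' \eqn{= BIC + 2E}; APPA per class is the mean posterior probability among
#' subjects MAP-assigned to that class (`NA` for empty classes);
#' `min_class_size` is the smallest MAP assignment count.
#'
#' @param model a converged `trajectory_fit` carrying its training posterior.
#' @param series optional series list; if supplied, posteriors are recomputed
#'   from it rather than taken from the fit.
#' @return data frame (one row) with `logLik`, `n_params`, `n_subjects`,
#'   `bic`, `entropy`, `icl`, `appa_min`, `min_class_size`, `valid`, plus an
#'   `appa` attribute with the per-class vector.
#' @export
compute_criteria <- function(model, series = NULL) {
  stopifnot(inherits(model, "trajectory_fit"))
  G <- model$spec$n_classes
  if (!is.null(series)) {
    pp <- posterior_probabilities(series, model, cutoff_day = 21)
    P <- as.matrix(pp[, paste0("ppa_", seq_len(G)), drop = FALSE])
  } else {
    P <- model$posterior
  }
  n <- nrow(P)
  bic <- -2 * model$loglik + model$n_params * log(model$n_subjects)
  Plog <- P * log(pmax(P, 1e-300))
  Plog[P == 0] <- 0
  entropy <- -sum(Plog)
  icl <- bic + 2 * entropy
  map <- max.col(P, ties.method = "first")
  appa <- vapply(seq_len(G), function(g)
    if (any(map == g)) mean(P[map == g, g]) else NA_real_, numeric(1))
  sizes <- tabulate(map, nbins = G)
  out <- data.frame(
    logLik = model$loglik, n_params = model$n_params,
    n_subjects = model$n_subjects, bic = bic, entropy = entropy, icl = icl,
    appa_min = if (all(is.na(appa))) NA_real_ else min(appa, na.rm = TRUE),
    min_class_size = min(sizes), valid = isTRUE(model$converged))
  attr(out, "appa") <- appa
  out
}

#' Fit every specification in an LCGA grid
#'
#' Convenience batch runner producing the criteria table consumed by
#' [select_shortlist()]. Fit failures become rows flagged `valid = FALSE`
#' rather than aborting the batch.
#'
#' @param labs curated long lab table.
#' @param grid an [enumerate_lcga_grid()] result.
#' @param subjects optional subject id vector fixing series order.
#' @param ... passed to [fit_trajectory_model()].
#' @return list with `criteria` (data frame, one row per grid row, including
#'   grid columns) and `fits` (list of `trajectory_fit` or `NULL`).
#' @export
fit_lcga_grid <- function(labs, grid, subjects = NULL, ...) {
  fits <- vector("list", nrow(grid))
  crit <- vector("list", nrow(grid))
  series_cache <- list()
  for (i in seq_len(nrow(grid))) {
    m <- grid$marker[i]
    if (is.null(series_cache[[m]]))
      series_cache[[m]] <- series_from_labs(labs, m, subjects)
    fit <- tryCatch(
      suppressWarnings(fit_trajectory_model(series_cache[[m]],
                                            grid_spec(grid, i), ...)),
      error = function(e) NULL)
    fits[[i]] <- fit
    crit[[i]] <- if (is.null(fit)) {
      data.frame(logLik = NA_real_, n_params = NA_integer_,
                 n_subjects = NA_integer_, bic = NA_real_,
                 entropy = NA_real_, icl = NA_real_, appa_min = NA_real_,
                 min_class_size = NA_integer_, valid = FALSE)
    } else compute_criteria(fit)
  }
  criteria <- cbind(grid[, c("marker", "n_classes", "link", "degree")],
                    do.call(rbind, crit))
  rownames(criteria) <- NULL
  list(criteria = criteria, fits = fits)
}

#' Shortlist candidate models per marker
#'
#' Applies the selection constraints (minimum APPA over classes, minimum MAP
#' class size), then ranks surviving specifications by ICL with BIC as
#' tiebreak. The best model plus any model within `delta` ICL of it are kept;
#' among such near-ties the fewest-parameter model is ranked first. If no
#' model satisfies the constraints for a marker, the best-BIC model is kept
#' with a warning.
#'
#' @param criteria criteria table from [fit_lcga_grid()].
#' @param appa_min APPA constraint applied to the per-class minimum.
#' @param min_class_size minimum MAP-assigned subjects per class.
#' @param delta ICL near-tie window.
#' @return list with `shortlist` (data frame with `rank` within marker and
#'   row index `grid_row` into `criteria`) and `ranking` (full constrained
#'   ranking).
#' @export
select_shortlist <- function(criteria, appa_min = 0.7, min_class_size = 20,
                             delta = 6) {
  stopifnot(nrow(criteria) >= 1)
  criteria$grid_row <- seq_len(nrow(criteria))
  out <- list(); rank_all <- list()
  for (m in unique(criteria$marker)) {
    cm <- criteria[criteria$marker == m & criteria$valid %in% TRUE, ,
                   drop = FALSE]
    ok <- cm[!is.na(cm$appa_min) & cm$appa_min >= appa_min &
               cm$min_class_size >= min_class_size, , drop = FALSE]
    if (nrow(ok) == 0) {
      warning("marker '", m, "': no model satisfies the APPA/class-size ",
              "constraints; falling back to the best-BIC model")
      cmv <- cm[!is.na(cm$bic), , drop = FALSE]
      if (nrow(cmv) == 0) next
      ok <- cmv[which.min(cmv$bic), , drop = FALSE]
    }
    ok <- ok[order(ok$icl, ok$bic), , drop = FALSE]
    keep <- ok[ok$icl <= ok$icl[1] + delta, , drop = FALSE]
    keep <- keep[order(keep$n_params, keep$icl, keep$bic), , drop = FALSE]
    keep$rank <- seq_len(nrow(keep))
    ok$rank <- seq_len(nrow(ok))
    out[[m]] <- keep
    rank_all[[m]] <- ok
  }
  list(shortlist = do.call(rbind, out), ranking = do.call(rbind, rank_all))
}

#' Refine shortlisted models with growth mixture models
#'
#' Each shortlisted LCGA specification is refit as a GMM: same class count
#' and link family, a natural-spline time basis of degrees of freedom equal
#' to the LCGA polynomial degree, and subject-level random effects. The final
#' model per marker is the converged refit with the best (lowest) ICL; if no
#' refit converges the best LCGA fit is returned, flagged.
#'
#' @param shortlist `shortlist` component of [select_shortlist()].
#' @param labs curated long lab table.
#' @param random_effects random-effect structure for the refits.
#' @param subjects optional subject id vector fixing series order.
#' @param ... passed to [fit_trajectory_model()].
#' @param lcga_fits optional list of grid fits (from [fit_lcga_grid()]) used
#'   for the fallback.
#' @return named list (per marker) with elements `fit`, `criteria`,
#'   `refined` (FALSE when the LCGA fallback was used).
#' @export
refine_with_gmm <- function(shortlist, labs,
                            random_effects = "intercept_slope",
                            subjects = NULL, lcga_fits = NULL, ...) {
  stopifnot(nrow(shortlist) >= 1)
  res <- list()
  for (m in unique(shortlist$marker)) {
    sm <- shortlist[shortlist$marker == m, , drop = FALSE]
    series <- series_from_labs(labs, m, subjects)
    best <- NULL; best_crit <- NULL
    for (j in seq_len(nrow(sm))) {
      spec <- trajectory_spec(
        m, sm$n_classes[j],
        time_basis("natural_spline", sm$degree[j], boundary = c(0, 21)),
        link_family = sm$link[j], random_effects = random_effects)
      fit <- tryCatch(
        suppressWarnings(fit_trajectory_model(series, spec, ...)),
        error = function(e) NULL)
      if (is.null(fit) || !isTRUE(fit$converged)) next
      crit <- compute_criteria(fit)
      if (is.null(best) || crit$icl < best_crit$icl) {
        best <- fit; best_crit <- crit
      }
    }
    if (is.null(best)) {
      warning("marker '", m, "': no GMM refit converged; keeping LCGA fit")
      if (!is.null(lcga_fits) && !is.null(lcga_fits[[as.character(sm$grid_row[1])]])) {
        best <- lcga_fits[[as.character(sm$grid_row[1])]]
      } else {
        spec <- trajectory_spec(
          m, sm$n_classes[1],
          time_basis("polynomial", sm$degree[1], boundary = c(0, 21)),
          link_family = sm$link[1], random_effects = "none")
        best <- suppressWarnings(fit_trajectory_model(series, spec, ...))
      }
      best_crit <- compute_criteria(best)
      res[[m]] <- list(fit = best, criteria = best_crit, refined = FALSE)
    } else {
      res[[m]] <- list(fit = best, criteria = best_crit, refined = TRUE)
    }
  }
  res
}
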