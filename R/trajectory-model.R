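#' Trajectory model specification
#'
#' Describes one candidate latent-class trajectory model for a single marker:
#' the number of classes, the time basis for the class mean curves, the link
#' family mapping observed values to the latent Gaussian scale, and the
#' random-effect structure (`"none"` for LCGA; `"intercept"` or
#' `"intercept_slope"` for GMM refinements).
#'
#' @param marker marker name.
#' @param n_classes number of latent classes, 1-5.
#' @param basis a [time_basis()] object.
#' @param link_family `"linear"`, `"ispline"` or `"beta"`.
#' @param random_effects `"none"`, `"intercept"` or `"intercept_slope"`.
#' @return object of class `trajectory_spec`.
#' @export
trajectory_spec <- function(marker, n_classes, basis,
                            link_family = c("linear", "ispline", "beta"),
                            random_effects = c("none", "intercept",
                                               "intercept_slope")) {
  link_family <- match.arg(link_family)
  random_effects <- match.arg(random_effects)
  n_classes <- as.integer(n_classes)
  if (n_classes < 1L || n_classes > 5L) stop("n_classes must be in 1..5")
  stopifnot(inherits(basis, "time_basis"))
  structure(list(marker = marker, n_classes = n_classes, basis = basis,
                 link_family = link_family, random_effects = random_effects),
            class = "trajectory_spec")
}

re_dim <- function(spec) {
  switch(spec$random_effects, none = 0L, intercept = 1L, intercept_slope = 2L)
}

#' Parameter count of a trajectory model specification
#'
#' Counting convention used for the BIC penalty: `G - 1` class-membership
#' logits, `G * (degree + 1)` fixed effects, `q(q+1)/2` random-effect
#' covariance terms (0 for LCGA), one residual variance, plus the nominal link
#' parameter count of the family (linear 2; quadratic I-spline with three
#' interior knots 6, i.e. five coefficients plus intercept; beta 4).
#'
#' @param spec a [trajectory_spec()].
#' @return integer parameter count.
#' @export
n_parameters <- function(spec) {
  stopifnot(inherits(spec, "trajectory_spec"))
  G <- spec$n_classes
  p <- spec$basis$degree + 1L
  q <- re_dim(spec)
  n_link <- switch(spec$link_family, linear = 2L, ispline = 6L, beta = 4L)
  (G - 1L) + G * p + (q * (q + 1L)) %/% 2L + 1L + n_link
}

## ---------------------------------------------------------------------------
## Internal series container: long labs -> per-subject times/values for one
## marker, plus cached design matrices.
## ---------------------------------------------------------------------------

#' Split a long lab table into per-subject series for one marker
#'
#' @param labs data frame with columns `subject_id`, `day`, `marker`, `value`.
#' @param marker marker to extract.
#' @param subjects optional subject ids to keep (in this order).
#' @return list of lists with elements `subject_id`, `times`, `values`; times
#'   sorted ascending within subject. Subjects with no events for the marker
#'   get empty series.
#' @export
series_from_labs <- function(labs, marker, subjects = NULL) {
  ev <- labs[labs$marker == marker, , drop = FALSE]
  if (is.null(subjects)) subjects <- sort(unique(ev$subject_id))
  idx <- split(seq_len(nrow(ev)), factor(ev$subject_id, levels = subjects))
  lapply(seq_along(subjects), function(i) {
    j <- idx[[i]]
    o <- order(ev$day[j])
    list(subject_id = subjects[i], times = ev$day[j][o],
         values = ev$value[j][o])
  })
}

## Stacked internal representation with design matrices for a given spec.
prepare_series_data <- function(series, spec, link) {
  keep <- vapply(series, function(s) length(s$times) > 0, logical(1))
  series <- series[keep]
  n <- length(series)
  if (n == 0L) stop("no non-empty series supplied")
  times <- unlist(lapply(series, `[[`, "times"))
  values <- unlist(lapply(series, `[[`, "values"))
  ni <- vapply(series, function(s) length(s$times), integer(1))
  subj <- rep(seq_len(n), ni)
  B <- evaluate_basis(times, spec$basis)
  q <- re_dim(spec)
  Z <- if (q > 0) cbind(1, times)[, seq_len(q), drop = FALSE] else NULL
  list(series = series, n = n, ni = ni, subj = subj, times = times,
       values = values, B = B, Z = Z, q = q,
       obs_by_subj = split(seq_along(values), subj),
       ids = vapply(series, function(s) as.character(s$subject_id),
                    character(1)),
       link = link)
}

logsumexp_rows <- function(m) {
  mx <- apply(m, 1, max)
  mx + log(rowSums(exp(m - mx)))
}

## Conditional log-likelihood matrix L[i, g] = log f(h_i | class g) for the
## latent-scale data h (Jacobian handled by the caller), given fixed effects
## beta (G x p), covariance D (q x q or NULL) and residual variance sigma2.
cond_loglik_matrix <- function(dat, h, beta, D, sigma2) {
  G <- nrow(beta)
  n <- dat$n
  L <- matrix(0, n, G)
  if (is.null(dat$Z) || dat$q == 0L) {
    mu <- dat$B %*% t(beta)               # n_obs x G
    ll <- stats::dnorm(h - mu, 0, sqrt(sigma2), log = TRUE)
    L <- rowsum(ll, dat$subj, reorder = TRUE)
  } else {
    for (i in seq_len(n)) {
      j <- dat$obs_by_subj[[i]]
      Zi <- dat$Z[j, , drop = FALSE]
      V <- Zi %*% D %*% t(Zi) + diag(sigma2, length(j))
      ch <- tryCatch(chol(V), error = function(e) NULL)
      if (is.null(ch)) {
        V <- V + diag(1e-8 * sum(diag(V)) / nrow(V), nrow(V))
        ch <- chol(V)
      }
      logdet <- 2 * sum(log(diag(ch)))
      Bi <- dat$B[j, , drop = FALSE]
      for (g in seq_len(G)) {
        r <- h[j] - drop(Bi %*% beta[g, ])
        z <- backsolve(ch, r, transpose = TRUE)
        L[i, g] <- -0.5 * (length(j) * log(2 * pi) + logdet + sum(z^2))
      }
    }
  }
  L
}

#' Marginal log-likelihood of a fitted trajectory model
#'
#' The observed-data log-likelihood of the latent-process mixture model: for
#' subject \eqn{i} with transformed values \eqn{h_{ij} = H(y_{ij})},
#' \deqn{\ell = \sum_i \log \sum_g \pi_g \,\phi(h_i;\, B_i\beta_g,\;
#'   Z_i D Z_i^\top + \sigma^2 I) \;+\; \sum_{ij} \log H'(y_{ij}),}
#' with \eqn{B_i} the time-basis design, \eqn{Z_i} the random-effect design
#' (absent for LCGA) and the final term the change-of-variables Jacobian of
#' the link.
#'
#' @param series list of per-subject series (see [series_from_labs()]); all
#'   must be non-empty.
#' @param model a fitted model from [fit_trajectory_model()], or any list with
#'   components `spec`, `link`, `pi`, `beta`, `D`, `sigma2`.
#' @return the marginal log-likelihood (scalar).
#' @export
marginal_loglik <- function(series, model) {
  dat <- prepare_series_data(series, model$spec, model$link)
  tr <- link_transform(dat$values, model$link, model$spec$marker)
  L <- cond_loglik_matrix(dat, tr$h, model$beta, model$D, model$sigma2)
  ll <- sum(logsumexp_rows(sweep(L, 2, log(model$pi), `+`))) +
    sum(tr$log_jacobian)
  if (!is.finite(ll)) stop("non-finite log-likelihood")
  ll
}

## Closed-form EM update of the variance components given responsibilities
## and fixed effects: per subject and class, posterior mean and covariance of
## the random effects feed the usual mixed-model M-step. `fix_sigma` keeps
## the residual variance at 1 for nonlinear link families, where the link
## carries the scale.
em_variance_update <- function(dat, h, w, beta, D, sigma2, fix_sigma) {
  G <- nrow(beta)
  q <- dat$q
  Dacc <- matrix(0, q, q)
  racc <- 0
  Dinv <- solve(D)
  for (i in seq_len(dat$n)) {
    j <- dat$obs_by_subj[[i]]
    Zi <- dat$Z[j, , drop = FALSE]
    Bi <- dat$B[j, , drop = FALSE]
    Ci <- solve(Dinv + crossprod(Zi) / sigma2)  # posterior cov of b_i
    trZCZ <- sum(diag(crossprod(Zi) %*% Ci))
    for (g in seq_len(G)) {
      r <- h[j] - drop(Bi %*% beta[g, ])
      bi <- drop(Ci %*% crossprod(Zi, r)) / sigma2
      Dacc <- Dacc + w[i, g] * (tcrossprod(bi) + Ci)
      racc <- racc + w[i, g] * (sum((r - drop(Zi %*% bi))^2) + trZCZ)
    }
  }
  list(D = Dacc / dat$n,
       sigma2 = if (fix_sigma) sigma2 else max(racc / length(h), 1e-10))
}

## Weighted GLS update for the class mean coefficients given responsibilities.
update_beta <- function(dat, h, w, D, sigma2) {
  G <- ncol(w)
  p <- ncol(dat$B)
  beta <- matrix(0, G, p)
  if (is.null(dat$Z) || dat$q == 0L) {
    for (g in seq_len(G)) {
      wg <- w[dat$subj, g]
      XtX <- crossprod(dat$B * wg, dat$B)
      Xty <- crossprod(dat$B * wg, h)
      beta[g, ] <- solve(XtX + diag(1e-10, p), Xty)
    }
  } else {
    XtX <- array(0, c(p, p, G)); Xty <- matrix(0, p, G)
    for (i in seq_len(dat$n)) {
      j <- dat$obs_by_subj[[i]]
      Zi <- dat$Z[j, , drop = FALSE]
      V <- Zi %*% D %*% t(Zi) + diag(sigma2, length(j))
      Vi <- tryCatch(solve(V), error = function(e)
        solve(V + diag(1e-8 * sum(diag(V)) / nrow(V), nrow(V))))
      Bi <- dat$B[j, , drop = FALSE]
      BtVi <- crossprod(Bi, Vi)
      for (g in seq_len(G)) {
        XtX[, , g] <- XtX[, , g] + w[i, g] * (BtVi %*% Bi)
        Xty[, g] <- Xty[, g] + w[i, g] * (BtVi %*% h[j])
      }
    }
    for (g in seq_len(G)) beta[g, ] <- solve(XtX[, , g] + diag(1e-10, p),
                                             Xty[, g])
  }
  beta
}

## Objective for the numeric link substep: full marginal loglik as a function
## of the link free parameters, with pi, beta and variance components fixed.
link_objective <- function(theta, dat, beta, logpi, link0, D, sigma2) {
  link <- link_set_params(link0, theta)
  tr <- tryCatch(link_transform(dat$values, link), error = function(e) NULL)
  if (is.null(tr) || any(!is.finite(tr$h)) || any(!is.finite(tr$log_jacobian)))
    return(-Inf)
  L <- tryCatch(cond_loglik_matrix(dat, tr$h, beta, D, sigma2),
                error = function(e) matrix(-Inf, dat$n, nrow(beta)))
  val <- sum(logsumexp_rows(sweep(L, 2, logpi, `+`))) + sum(tr$log_jacobian)
  if (!is.finite(val)) -Inf else val
}

## Per-subject OLS coefficients on the latent scale, used to seed class means.
subject_ols <- function(dat, h) {
  p <- ncol(dat$B)
  pooled <- solve(crossprod(dat$B) + diag(1e-8, p), crossprod(dat$B, h))
  obs_by_subj <- split(seq_along(h), dat$subj)
  t(vapply(seq_len(dat$n), function(i) {
    j <- obs_by_subj[[i]]
    if (length(j) <= p) return(drop(pooled))
    Bi <- dat$B[j, , drop = FALSE]
    drop(solve(crossprod(Bi) + diag(1e-8, p), crossprod(Bi, h[j])))
  }, numeric(p)))
}

#' Fit a latent-class trajectory model
#'
#' Maximizes the marginal likelihood (see [marginal_loglik()]) by multi-start
#' coordinate ascent: an EM step updates class responsibilities and the
#' membership probabilities, a closed-form weighted generalized-least-squares
#' step updates the class mean coefficients, and a quasi-Newton substep
#' updates the variance components and link parameters on log/Cholesky scales.
#' The first start seeds class means by k-means on per-subject least-squares
#' coefficients; remaining starts are random perturbations. Classes in the
#' returned fit are re-ordered canonically: descending number of MAP-assigned
#' subjects, ties broken by fitted latent level at day 0.
#'
#' @param series list of per-subject series; empty series are dropped with a
#'   message.
#' @param spec a [trajectory_spec()].
#' @param n_starts number of starts (first is k-means-seeded).
#' @param max_iter maximum coordinate-ascent iterations per start.
#' @param tol relative log-likelihood convergence tolerance.
#' @param seed integer seed controlling start randomization.
#' @return object of class `trajectory_fit` with elements `spec`, `link`,
#'   `zeta` (membership logits, class G reference), `pi`, `beta`, `D`,
#'   `sigma2`, `loglik`, `n_params`, `converged`, `n_subjects`,
#'   `class_counts`, `posterior` (n x G responsibilities at the optimum).
#' @export
fit_trajectory_model <- function(series, spec, n_starts = 5L, max_iter = 500L,
                                 tol = 1e-6, seed = 1L) {
  stopifnot(inherits(spec, "trajectory_spec"))
  n_empty <- sum(vapply(series, function(s) length(s$times) == 0, logical(1)))
  if (n_empty > 0) message(n_empty, " empty series dropped before fitting")
  link0 <- init_link(spec$link_family,
                     unlist(lapply(series, `[[`, "values")))
  if (spec$basis$kind == "natural_spline" && is.null(spec$basis$knots))
    spec$basis$knots <- spline_knots_from_times(
      unlist(lapply(series, `[[`, "times")), spec$basis$degree)
  dat <- prepare_series_data(series, spec, link0)
  G <- spec$n_classes
  if (dat$n < 20L * G)
    warning("fewer than ", 20L * G, " subjects for G = ", G, " classes")

  tr0 <- link_transform(dat$values, link0, spec$marker)
  ols <- subject_ols(dat, tr0$h)
  resid0 <- tr0$h - rowSums(dat$B * ols[dat$subj, , drop = FALSE])
  sigma2_0 <- max(stats::var(resid0), 1e-6)

  old_seed <- get0(".Random.seed", globalenv(), ifnotfound = NULL)
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                         envir = globalenv()))
  set.seed(seed)

  best <- NULL
  for (s in seq_len(n_starts)) {
    init <- start_values(ols, G, s, sigma2_0)
    fit <- tryCatch(
      em_one_start(dat, spec, link0, init, max_iter, tol),
      error = function(e) NULL)
    if (!is.null(fit) && (is.null(best) || fit$loglik > best$loglik))
      best <- fit
    if (G == 1L) break  # deterministic: no class-label multimodality
  }
  if (is.null(best)) stop("all starts failed for marker '", spec$marker, "'")
  finalize_fit(best, dat, spec)
}

start_values <- function(ols, G, start_index, sigma2_0) {
  p <- ncol(ols)
  if (G == 1L) {
    beta <- matrix(colMeans(ols), 1, p)
  } else if (start_index == 1L) {
    km <- stats::kmeans(ols, centers = G, nstart = 5)
    beta <- km$centers
  } else {
    ctr <- ols[sample.int(nrow(ols), G), , drop = FALSE]
    beta <- ctr + matrix(stats::rnorm(G * p, sd = 0.25 * apply(ols, 2, stats::sd) + 1e-6),
                         G, p, byrow = TRUE)
  }
  list(beta = unname(beta), pi = rep(1 / G, G), sigma2 = sigma2_0)
}

em_one_start <- function(dat, spec, link0, init, max_iter, tol,
                         burnin = 10L) {
  G <- spec$n_classes
  q <- dat$q
  family <- spec$link_family
  beta <- init$beta
  pi <- init$pi
  sigma2 <- if (family == "linear") init$sigma2 else 1
  D <- if (q > 0) diag(c(0.1, 0.01)[seq_len(q)] * max(init$sigma2, 0.1),
                       q) else NULL
  link <- link0
  ll_old <- -Inf
  converged <- FALSE
  collapsed <- FALSE
  w <- NULL
  for (iter in seq_len(max_iter)) {
    tr <- link_transform(dat$values, link, spec$marker)
    L <- cond_loglik_matrix(dat, tr$h, beta, D, sigma2)
    A <- sweep(L, 2, log(pi), `+`)
    lse <- logsumexp_rows(A)
    ll <- sum(lse) + sum(tr$log_jacobian)
    w <- exp(A - lse)
    burnin_eff <- if (family == "linear" && q == 0L) 0L else burnin
    if (iter > burnin_eff + 1L && is.finite(ll_old) &&
        abs(ll - ll_old) < tol * (abs(ll_old) + 1e-3)) {
      converged <- TRUE
      break
    }
    ll_old <- ll
    pi <- pmax(colMeans(w), 1e-12)
    pi <- pi / sum(pi)
    if (min(pi) < 1 / (10 * dat$n)) { collapsed <- TRUE; break }
    beta <- update_beta(dat, tr$h, w, D, sigma2)
    if (family == "linear" && q == 0L) {
      # closed-form residual variance update
      res2 <- (tr$h - dat$B %*% t(beta))^2
      sigma2 <- max(sum(res2 * w[dat$subj, , drop = FALSE]) /
                      length(tr$h), 1e-10)
      next
    }
    if (iter <= burnin) next  # let classes form before freeing variances/link
    if (q > 0L) {
      up <- em_variance_update(dat, tr$h, w, beta, D, sigma2,
                               fix_sigma = family != "linear")
      D <- up$D; sigma2 <- up$sigma2
    }
    if (family != "linear" && (iter - burnin) %% 3L == 1L) {
      th <- link_free_params(link)
      opt <- stats::optim(th, link_objective, dat = dat, beta = beta,
                          logpi = log(pi), link0 = link, D = D,
                          sigma2 = sigma2, method = "Nelder-Mead",
                          control = list(fnscale = -1, maxit = 30))
      link <- link_set_params(link, opt$par)
    }
  }
  list(beta = beta, pi = pi, sigma2 = sigma2, D = D, link = link,
       loglik = ll, posterior = w, converged = converged && !collapsed,
       collapsed = collapsed, n_iter = iter)
}

finalize_fit <- function(fit, dat, spec) {
  G <- spec$n_classes
  map <- max.col(fit$posterior, ties.method = "first")
  counts <- tabulate(map, nbins = G)
  level0 <- drop(fit$beta %*% evaluate_basis(0, spec$basis)[1, ])
  ord <- order(-counts, level0)
  beta <- fit$beta[ord, , drop = FALSE]
  pi <- fit$pi[ord]
  posterior <- fit$posterior[, ord, drop = FALSE]
  map <- max.col(posterior, ties.method = "first")
  zeta <- log(pi[-G] / pi[G])
  structure(list(
    spec = spec, link = fit$link, zeta = zeta, pi = pi, beta = beta,
    D = fit$D, sigma2 = fit$sigma2, loglik = fit$loglik,
    n_params = n_parameters(spec), converged = fit$converged,
    n_subjects = dat$n, class_counts = tabulate(map, nbins = G),
    posterior = posterior, subject_ids = dat$ids,
    n_iter = fit$n_iter), class = "trajectory_fit")
}

#' @export
print.trajectory_fit <- function(x, ...) {
  cat("Latent-class trajectory model: marker '", x$spec$marker, "'\n", sep = "")
  cat("  classes:", x$spec$n_classes,
      "| basis:", x$spec$basis$kind, "degree", x$spec$basis$degree,
      "| link:", x$spec$link_family,
      "| random effects:", x$spec$random_effects, "\n")
  cat("  logLik:", format(x$loglik), " params:", x$n_params,
      " subjects:", x$n_subjects,
      " converged:", x$converged, "\n")
  cat("  class proportions:", paste(round(x$pi, 3), collapse = ", "), "\n")
  invisible(x)
}

#' Posterior class-membership probabilities at a landmark cutoff
#'
#' Bayes-rule posterior probability of assignment (PPA) for each class given
#' a subject's observations up to `cutoff_day`. The link Jacobian cancels
#' across classes. Subjects with no observations in the window receive the
#' model's prior class probabilities.
#'
#' @param series list of per-subject series (possibly empty).
#' @param model a `trajectory_fit`.
#' @param cutoff_day landmark day in (0, 21]; observations with
#'   `time <= cutoff_day` are used.
#' @return data frame with `subject_id`, `cutoff_day`, one `ppa_<g>` column
#'   per class, and `map_class` (ties resolved to the lowest class index).
#' @export
posterior_probabilities <- function(series, model, cutoff_day = 21) {
  stopifnot(inherits(model, "trajectory_fit"),
            cutoff_day > 0, cutoff_day <= 21)
  G <- model$spec$n_classes
  trunc <- lapply(series, function(s) {
    keep <- s$times <= cutoff_day
    list(subject_id = s$subject_id, times = s$times[keep],
         values = s$values[keep])
  })
  nonempty <- vapply(trunc, function(s) length(s$times) > 0, logical(1))
  P <- matrix(model$pi, nrow = length(series), ncol = G, byrow = TRUE)
  if (any(nonempty)) {
    dat <- prepare_series_data(trunc[nonempty], model$spec, model$link)
    tr <- link_transform(dat$values, model$link, model$spec$marker)
    L <- cond_loglik_matrix(dat, tr$h, model$beta, model$D, model$sigma2)
    A <- sweep(L, 2, log(model$pi), `+`)
    P[nonempty, ] <- exp(A - logsumexp_rows(A))
  }
  map <- apply(P, 1, which.max)  # which.max takes the lowest index on ties
  out <- data.frame(
    subject_id = vapply(series, function(s) as.character(s$subject_id),
                        character(1)),
    cutoff_day = cutoff_day, P, map_class = as.integer(map),
    stringsAsFactors = FALSE)
  names(out)[2 + seq_len(G)] <- paste0("ppa_", seq_len(G))
  out
}

#' Serialize / restore a fitted trajectory model as JSON
#'
#' Plain-text round trip of the specification, link parameters, estimated
#' parameters and fit statistics, so selected models can be frozen before the
#' prediction stage.
#'
#' @param model a `trajectory_fit`.
#' @param path file path to write to / read from.
#' @return `read_trajectory_fit()` returns a `trajectory_fit` (without the
#'   training posterior matrix).
#' @export
write_trajectory_fit <- function(model, path) {
  stopifnot(inherits(model, "trajectory_fit"))
  x <- model
  x$posterior <- NULL
  x$beta <- as.data.frame(x$beta)
  x$D <- if (is.null(x$D)) NULL else as.data.frame(x$D)
  class(x) <- NULL
  x$spec <- unclass(x$spec)
  x$spec$basis <- unclass(x$spec$basis)
  x$link_class <- class(model$link)
  x$link <- unclass(x$link)
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_trajectory_fit
#' @export
read_trajectory_fit <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  basis <- structure(x$spec$basis, class = "time_basis")
  basis$boundary <- as.numeric(basis$boundary)
  if (!is.null(basis$knots)) basis$knots <- as.numeric(basis$knots)
  spec <- trajectory_spec(x$spec$marker, x$spec$n_classes, basis,
                          x$spec$link_family, x$spec$random_effects)
  link <- structure(x$link, class = x$link_class)
  if (!is.null(link$range)) link$range <- as.numeric(link$range)
  if (!is.null(link$boundary)) link$boundary <- as.numeric(link$boundary)
  structure(list(
    spec = spec, link = link, zeta = as.numeric(x$zeta),
    pi = as.numeric(x$pi), beta = as.matrix(x$beta),
    D = if (is.null(x$D)) NULL else as.matrix(x$D),
    sigma2 = x$sigma2, loglik = x$loglik, n_params = x$n_params,
    converged = x$converged, n_subjects = x$n_subjects,
    class_counts = as.integer(x$class_counts), posterior = NULL,
    subject_ids = x$subject_ids, n_iter = x$n_iter),
    class = "trajectory_fit")
}
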