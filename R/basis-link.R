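#' Time basis for trajectory mean curves
#'
#' Defines the fixed-effect design in time used by the latent-class trajectory
#' models: raw polynomials of degree 1-3 for the exploratory (LCGA) stage, and
#' natural cubic splines for the refinement (GMM) stage. Evaluation always
#' includes an intercept column, so the basis dimension is `degree + 1`.
#'
#' @param kind `"polynomial"` or `"natural_spline"`.
#' @param degree polynomial degree, or spline degrees of freedom (number of
#'   non-intercept columns).
#' @param knots interior knot locations in days (natural spline only). If
#'   `NULL`, knots are placed at quantiles of observation times at fit time via
#'   [spline_knots_from_times()].
#' @param boundary boundary knots in days; the spline is linear beyond them.
#' @return An object of class `time_basis`.
#' @seealso [evaluate_basis()]
#' @export
time_basis <- function(kind = c("polynomial", "natural_spline"), degree = 1L,
                       knots = NULL, boundary = c(0, 21)) {
  kind <- match.arg(kind)
  degree <- as.integer(degree)
  if (kind == "polynomial" && !(degree %in% 1:3))
    stop("polynomial degree must be 1, 2 or 3")
  if (degree < 1L) stop("degree must be >= 1")
  if (!is.null(knots) && any(knots <= boundary[1] | knots >= boundary[2]))
    stop("interior knots must lie strictly inside the boundary")
  structure(list(kind = kind, degree = degree, knots = knots,
                 boundary = as.numeric(boundary)),
            class = "time_basis")
}

#' Interior spline knots from pooled observation times
#'
#' Places `df - 1` interior knots at equally spaced quantiles of the pooled
#' observation times, the convention used when a polynomial LCGA basis is
#' promoted to a natural-spline GMM basis of matching dimension.
#'
#' @param times numeric vector of observation days.
#' @param df spline degrees of freedom.
#' @return numeric vector of `df - 1` interior knots (possibly empty).
#' @export
spline_knots_from_times <- function(times, df) {
  n_int <- df - 1L
  if (n_int < 1L) return(numeric(0))
  probs <- seq_len(n_int) / (n_int + 1)
  as.numeric(stats::quantile(times, probs = probs, type = 7, names = FALSE))
}

#' Evaluate a time basis
#'
#' @param t numeric vector of days.
#' @param basis a [time_basis()] object.
#' @return matrix with `length(t)` rows and `degree + 1` columns; first column
#'   is the intercept.
#' @export
evaluate_basis <- function(t, basis) {
  stopifnot(inherits(basis, "time_basis"), all(is.finite(t)))
  if (basis$kind == "polynomial") {
    out <- outer(t, 0:basis$degree, `^`)
  } else {
    knots <- basis$knots
    if (is.null(knots)) knots <- spline_knots_from_times(
      seq(basis$boundary[1], basis$boundary[2], length.out = 64), basis$degree)
    ns <- splines::ns(t, knots = if (length(knots)) knots else NULL,
                      Boundary.knots = basis$boundary)
    if (ncol(ns) != basis$degree)
      stop("natural spline dimension mismatch: got ", ncol(ns),
           ", expected ", basis$degree)
    out <- cbind(1, unclass(ns))
  }
  dimnames(out) <- NULL
  out
}

## ---------------------------------------------------------------------------
## Link functions: monotone transforms H(y; eta) mapping an observed marker to
## the latent Gaussian-process scale. Three families mirror the modeling stage:
## identity for approximately Gaussian markers, a monotone quadratic I-spline,
## and a rescaled beta CDF for skewed/bounded shapes.
## ---------------------------------------------------------------------------

#' Linear (identity) link
#'
#' Fixed at the identity: location 0, scale 1. With a free residual variance
#' and free class intercepts, a free affine link would not be identifiable, so
#' the linear family estimates no link parameters and the residual standard
#' deviation is estimated instead.
#' @return object of class `c("link_linear", "link_function")`.
#' @export
link_linear <- function() {
  structure(list(family = "linear", eta = c(0, 1)),
            class = c("link_linear", "link_function"))
}

#' Monotone quadratic I-spline link
#'
#' \eqn{H(y) = \sum_k c_k^2 I_k(y)} where the \eqn{I_k} are quadratic
#' I-splines (integrated linear M-splines) on the marker's value range with
#' three interior knots; squaring the stored coefficients enforces
#' monotonicity. The intercept is fixed at 0 (class intercepts absorb
#' location) and the residual variance is fixed at 1 (the coefficients carry
#' the scale).
#'
#' @param knots three interior knots on the value scale (defaults set from
#'   value quantiles at fit time).
#' @param boundary value-range boundary (min, max).
#' @param coef_raw unconstrained coefficients, squared on use; length
#'   `length(knots) + 2`.
#' @export
link_ispline <- function(knots, boundary, coef_raw = NULL) {
  stopifnot(length(boundary) == 2, boundary[1] < boundary[2],
            all(knots > boundary[1]), all(knots < boundary[2]))
  nb <- length(knots) + 2L
  if (is.null(coef_raw)) coef_raw <- rep(1 / sqrt(nb), nb)
  stopifnot(length(coef_raw) == nb)
  structure(list(family = "ispline", knots = as.numeric(knots),
                 boundary = as.numeric(boundary),
                 coef_raw = as.numeric(coef_raw)),
            class = c("link_ispline", "link_function"))
}

#' Beta-CDF link
#'
#' Values are first rescaled to the open unit interval,
#' \eqn{y^* = (y - y_{min} + \delta) / (y_{max} - y_{min} + 2\delta)} with
#' buffer \eqn{\delta} a small fraction of the value range, then transformed by
#' \eqn{H(y) = (F_{Beta}(y^*; a, b) - loc) / scale}. The location is fixed at
#' 0 for identifiability; shape parameters and scale are estimated with the
#' residual variance fixed at 1.
#'
#' @param shape1,shape2 beta shape parameters, both > 0.
#' @param scale positive scale; smaller values spread the latent scale.
#' @param range observed value range `c(min, max)` used for rescaling.
#' @param location latent-scale location, fixed at 0 during estimation.
#' @param delta_frac rescaling buffer as a fraction of the value range.
#' @export
link_beta <- function(shape1 = 1, shape2 = 1, scale = 0.25,
                      range, location = 0, delta_frac = 1e-3) {
  stopifnot(shape1 > 0, shape2 > 0, scale > 0,
            length(range) == 2, range[1] < range[2])
  structure(list(family = "beta", shape1 = shape1, shape2 = shape2,
                 scale = scale, location = location,
                 range = as.numeric(range),
                 delta = delta_frac * diff(range)),
            class = c("link_beta", "link_function"))
}

## Quadratic I-spline design matrix (and first derivative) via the cumulative
## B-spline identity: quadratic I-splines are right-cumulative sums of the
## degree-2 B-splines on the same knot sequence, dropping the constant sum.
ispline_design <- function(y, knots, boundary, deriv = 0L) {
  ord <- 3L  # quadratic B-splines
  y <- pmin(pmax(y, boundary[1]), boundary[2])
  aug <- c(rep(boundary[1], ord), knots, rep(boundary[2], ord))
  B <- splines::splineDesign(aug, y, ord = ord, derivs = rep(deriv, length(y)),
                             outer.ok = FALSE)
  nb <- ncol(B)  # length(knots) + ord - 1
  # right-cumulative sums, columns 2..nb (column 1 sums to the constant 1)
  out <- B %*% lower.tri(matrix(1, nb, nb), diag = TRUE)
  out[, 2:nb, drop = FALSE]
}

#' Apply a link transform
#'
#' Maps observed marker values to the latent scale and returns the
#' log-Jacobian \eqn{\log H'(y)} needed by the likelihood.
#'
#' @param y numeric vector of observed values.
#' @param link a link object.
#' @param marker optional marker name used in range-error messages.
#' @return list with components `h` and `log_jacobian`, both vectors.
#' @export
link_transform <- function(y, link, marker = "") {
  UseMethod("link_transform", link)
}

#' @export
link_transform.link_linear <- function(y, link, marker = "") {
  list(h = (y - link$eta[1]) / link$eta[2],
       log_jacobian = rep(-log(link$eta[2]), length(y)))
}

#' @export
link_transform.link_ispline <- function(y, link, marker = "") {
  if (any(y < link$boundary[1] - 1e-9 | y > link$boundary[2] + 1e-9))
    stop("value outside I-spline link range for marker '", marker, "'")
  cf <- link$coef_raw^2
  h <- drop(ispline_design(y, link$knots, link$boundary) %*% cf)
  hp <- drop(ispline_design(y, link$knots, link$boundary, deriv = 1L) %*% cf)
  if (any(hp <= 0))
    stop("I-spline link not strictly increasing at some values (marker '",
         marker, "')")
  list(h = h, log_jacobian = log(hp))
}

#' @export
link_transform.link_beta <- function(y, link, marker = "") {
  width <- diff(link$range) + 2 * link$delta
  ystar <- (y - link$range[1] + link$delta) / width
  if (any(ystar <= 0 | ystar >= 1))
    stop("value outside beta link range for marker '", marker,
         "': observed ", signif(y[which(ystar <= 0 | ystar >= 1)[1]], 4))
  h <- (stats::pbeta(ystar, link$shape1, link$shape2) - link$location) /
    link$scale
  lj <- stats::dbeta(ystar, link$shape1, link$shape2, log = TRUE) -
    log(width) - log(link$scale)
  list(h = h, log_jacobian = lj)
}

#' Invert a link transform
#'
#' Maps latent-scale values back to the observed scale; used by the synthetic
#' cohort generator. Errors if a latent value falls outside the invertible
#' range of the link, naming the marker.
#'
#' @inheritParams link_transform
#' @param h numeric vector of latent-scale values.
#' @return numeric vector of observed-scale values.
#' @export
link_inverse <- function(h, link, marker = "") {
  UseMethod("link_inverse", link)
}

#' @export
link_inverse.link_linear <- function(h, link, marker = "") {
  link$eta[1] + link$eta[2] * h
}

#' @export
link_inverse.link_beta <- function(h, link, marker = "") {
  u <- link$scale * h + link$location
  if (any(u <= 0 | u >= 1))
    stop("latent value not invertible under beta link for marker '", marker,
         "' (u = ", signif(u[which(u <= 0 | u >= 1)[1]], 4), ")")
  ystar <- stats::qbeta(u, link$shape1, link$shape2)
  width <- diff(link$range) + 2 * link$delta
  ystar * width + link$range[1] - link$delta
}

#' @export
link_inverse.link_ispline <- function(h, link, marker = "") {
  grid_y <- seq(link$boundary[1], link$boundary[2], length.out = 512)
  grid_h <- drop(ispline_design(grid_y, link$knots, link$boundary) %*%
                   link$coef_raw^2)
  if (any(h < min(grid_h) - 1e-9 | h > max(grid_h) + 1e-9))
    stop("latent value not invertible under I-spline link for marker '",
         marker, "'")
  stats::approx(grid_h, grid_y, xout = h, rule = 2)$y
}

## Free-parameter packing used by the fitter (see fit_trajectory_model).
link_free_params <- function(link) {
  switch(link$family,
         linear = numeric(0),
         ispline = link$coef_raw,
         beta = c(log(link$shape1), log(link$shape2), log(link$scale)))
}

link_set_params <- function(link, theta) {
  switch(link$family,
         linear = link,
         ispline = { link$coef_raw <- theta; link },
         beta = { link$shape1 <- exp(theta[1]); link$shape2 <- exp(theta[2])
                  link$scale <- exp(theta[3]); link })
}

## Initial link object for a marker's pooled values.
init_link <- function(family, values) {
  if (family == "linear") return(link_linear())
  rng <- range(values)
  if (family == "ispline") {
    kn <- as.numeric(stats::quantile(values, c(0.25, 0.5, 0.75), names = FALSE))
    # collapse duplicate knots away from ties
    kn <- pmin(pmax(kn, rng[1] + 1e-6 * diff(rng)), rng[2] - 1e-6 * diff(rng))
    if (any(diff(kn) <= 0)) kn <- rng[1] + diff(rng) * c(0.25, 0.5, 0.75)
    # total rise approximately the standardized range so H has unit-ish sd
    rise <- diff(rng) / max(stats::sd(values), 1e-8)
    link_ispline(knots = kn, boundary = rng,
                 coef_raw = rep(sqrt(rise / 5), 5))
  } else {
    delta <- 1e-3 * diff(rng)
    width <- diff(rng) + 2 * delta
    ystar <- (values - rng[1] + delta) / width
    link_beta(shape1 = 1, shape2 = 1,
              scale = max(stats::sd(ystar), 1e-3), range = rng)
  }
}
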