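#' Remove zero-valued lab events
#'
#' Observations recorded as exactly 0 are biologically implausible for the
#' modeled markers and are removed before outlier fencing.
#'
#' @param events long lab table (`subject_id`, `day`, `marker`, `value`).
#' @return list with `events` (zeros removed) and `n_removed` (named per
#'   marker, markers with no zeros included with count 0).
#' @export
remove_zero_values <- function(events) {
  is_zero <- events$value == 0
  markers <- unique(events$marker)
  n_removed <- vapply(markers, function(m)
    sum(is_zero & events$marker == m), numeric(1))
  list(events = events[!is_zero, , drop = FALSE],
       n_removed = n_removed)
}

#' Quantile-fence outlier filter
#'
#' A modified Tukey rule: per marker, pooled over subjects, values are
#' retained iff they lie inside
#' \eqn{[Q_{20} - m (Q_{80} - Q_{20}),\; Q_{80} + m (Q_{80} - Q_{20})]}
#' (bounds inclusive), with quantiles by linear interpolation between order
#' statistics. Using the 20th/80th percentiles instead of quartiles loosens
#' the fence for skewed marker distributions.
#'
#' @param values numeric vector for one marker (pooled across subjects).
#' @param lower_q,upper_q fence quantiles.
#' @param multiplier fence multiplier `m`.
#' @return list with `retained` (logical vector), `fence` (low, high) and
#'   counts `n_input`, `n_removed`.
#' @export
tukey_fence_filter <- function(values, lower_q = 0.20, upper_q = 0.80,
                               multiplier = 1.5) {
  stopifnot(length(values) >= 1, all(is.finite(values)))
  q <- stats::quantile(values, c(lower_q, upper_q), type = 7, names = FALSE)
  spread <- q[2] - q[1]
  fence <- c(q[1] - multiplier * spread, q[2] + multiplier * spread)
  retained <- values >= fence[1] & values <= fence[2]
  list(retained = retained, fence = fence,
       n_input = length(values), n_removed = sum(!retained))
}

#' Select the most commonly measured markers
#'
#' Ranks markers by the fraction of subjects with at least one measurement
#' and returns the top `k`; ties are broken by marker name.
#'
#' @param events long lab table.
#' @param k number of markers to keep.
#' @return list with `markers` (selected names) and `coverage` (data frame of
#'   per-marker subject fractions, all markers, sorted).
#' @export
select_common_markers <- function(events, k = 20) {
  stopifnot(nrow(events) > 0)
  n_subjects <- length(unique(events$subject_id))
  tab <- unique(events[, c("subject_id", "marker")])
  frac <- table(tab$marker) / n_subjects
  cov <- data.frame(marker = names(frac), fraction = as.numeric(frac),
                    stringsAsFactors = FALSE)
  cov <- cov[order(-cov$fraction, cov$marker), , drop = FALSE]
  rownames(cov) <- NULL
  if (nrow(cov) < k) {
    warning("only ", nrow(cov), " distinct markers available; returning all")
    k <- nrow(cov)
  }
  list(markers = cov$marker[seq_len(k)], coverage = cov)
}

#' Apply the time-window and minimum-measurement inclusion rules
#'
#' Events after `max_day` (exclusive) are dropped first; subjects are then
#' retained only if every selected marker has at least `min_measures`
#' remaining events. Day 0 is admission and the day-`max_day` boundary is
#' inclusive.
#'
#' @param events long lab table (already zero- and fence-filtered).
#' @param markers selected marker names.
#' @param min_measures minimum events per marker per subject.
#' @param max_day truncation day.
#' @return list with `events` (truncated, selected markers, retained subjects
#'   only) and `inclusion` (per-subject data frame with `included` flag and
#'   `reason` for exclusions).
#' @export
apply_inclusion_rules <- function(events, markers, min_measures = 3,
                                  max_day = 21) {
  stopifnot(length(markers) > 0)
  ev <- events[events$day <= max_day & events$marker %in% markers, ,
               drop = FALSE]
  subjects <- unique(events$subject_id)
  counts <- table(factor(ev$subject_id, levels = subjects),
                  factor(ev$marker, levels = markers))
  ok <- apply(counts >= min_measures, 1, all)
  reason <- ifelse(ok, "", "insufficient measures")
  inclusion <- data.frame(subject_id = subjects, included = as.vector(ok),
                          reason = reason, stringsAsFactors = FALSE)
  if (!any(ok))
    stop("no subjects satisfy the inclusion rules; relax min_measures, ",
         "max_day or the sampling configuration")
  list(events = ev[ev$subject_id %in% subjects[ok], , drop = FALSE],
       inclusion = inclusion)
}

#' Full laboratory preprocessing pipeline
#'
#' Fixed order: zero removal, quantile-fence outlier filter per marker,
#' selection of the `top_k` most common markers, day-window truncation with
#' the minimum-measurement inclusion rule. Rerunning the pipeline on its own
#' output changes nothing.
#'
#' @param events long lab table.
#' @param top_k number of markers to keep.
#' @param min_measures,max_day inclusion rules (see
#'   [apply_inclusion_rules()]).
#' @param lower_q,upper_q,multiplier fence parameters (see
#'   [tukey_fence_filter()]).
#' @return list with `events` (curated table), `markers`, `filter_report`
#'   (one row per marker: counts and fences), `coverage`, `inclusion`.
#' @export
preprocess_labs <- function(events, top_k = 20, min_measures = 3,
                            max_day = 21, lower_q = 0.20, upper_q = 0.80,
                            multiplier = 1.5) {
  z <- remove_zero_values(events)
  ev <- z$events
  markers_all <- sort(unique(events$marker))
  report <- vector("list", length(markers_all))
  keep <- rep(TRUE, nrow(ev))
  for (i in seq_along(markers_all)) {
    m <- markers_all[i]
    idx <- which(ev$marker == m)
    if (!length(idx)) {
      report[[i]] <- data.frame(marker = m, n_input = 0, n_zero_removed =
                                  z$n_removed[[m]] %||% 0,
                                n_fence_removed = 0, fence_low = NA_real_,
                                fence_high = NA_real_, n_retained = 0)
      next
    }
    f <- tukey_fence_filter(ev$value[idx], lower_q, upper_q, multiplier)
    keep[idx] <- f$retained
    nz <- if (m %in% names(z$n_removed)) z$n_removed[[m]] else 0
    report[[i]] <- data.frame(
      marker = m, n_input = f$n_input + nz, n_zero_removed = nz,
      n_fence_removed = f$n_removed, fence_low = f$fence[1],
      fence_high = f$fence[2], n_retained = f$n_input - f$n_removed)
  }
  ev <- ev[keep, , drop = FALSE]
  sel <- select_common_markers(ev, k = top_k)
  incl <- apply_inclusion_rules(ev, sel$markers, min_measures, max_day)
  list(events = incl$events, markers = sel$markers,
       filter_report = do.call(rbind, report), coverage = sel$coverage,
       inclusion = incl$inclusion)
}
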