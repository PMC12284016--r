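#' Univariate association between class membership and a covariate
#'
#' Continuous covariates use one-way ANOVA (equivalent to a two-sample t-test
#' when there are two classes) or Kruskal-Wallis as a configurable
#' alternative; categorical covariates use Fisher's exact test, switching to
#' a seeded Monte-Carlo p-value (2000 replicates) for tables larger than
#' 2 x 2. Degenerate covariates (a single level or zero variance) are marked
#' untestable rather than erroring.
#'
#' @param class_labels integer/factor class assignment per subject.
#' @param covariate covariate values per subject.
#' @param kind `"continuous"` or `"categorical"`.
#' @param continuous_test `"anova"` (default) or `"kruskal"`.
#' @param B Monte-Carlo replicates for large Fisher tables.
#' @param seed seed for the Monte-Carlo p-value.
#' @return list with `test`, `statistic`, `p_value`, `untestable`.
#' @export
test_association <- function(class_labels, covariate,
                             kind = c("continuous", "categorical"),
                             continuous_test = c("anova", "kruskal"),
                             B = 2000, seed = 1L) {
  kind <- match.arg(kind)
  continuous_test <- match.arg(continuous_test)
  cl <- factor(class_labels)
  ok <- !is.na(covariate) & !is.na(cl)
  cl <- droplevels(cl[ok]); covariate <- covariate[ok]
  if (nlevels(cl) < 2 || any(table(cl) < 2))
    return(list(test = "none", statistic = NA_real_, p_value = NA_real_,
                untestable = TRUE))
  if (kind == "continuous") {
    if (stats::var(covariate) == 0)
      return(list(test = "none", statistic = NA_real_, p_value = NA_real_,
                  untestable = TRUE))
    if (continuous_test == "anova") {
      a <- stats::anova(stats::lm(covariate ~ cl))
      list(test = "anova", statistic = a$`F value`[1],
           p_value = a$`Pr(>F)`[1], untestable = FALSE)
    } else {
      k <- stats::kruskal.test(covariate, cl)
      list(test = "kruskal", statistic = unname(k$statistic),
           p_value = k$p.value, untestable = FALSE)
    }
  } else {
    tab <- table(cl, factor(covariate))
    if (any(dim(tab) < 2))
      return(list(test = "none", statistic = NA_real_, p_value = NA_real_,
                  untestable = TRUE))
    if (all(dim(tab) == 2)) {
      f <- stats::fisher.test(tab)
      list(test = "fisher", statistic = unname(f$estimate %||% NA_real_),
           p_value = f$p.value, untestable = FALSE)
    } else {
      old_seed <- get0(".Random.seed", globalenv(), ifnotfound = NULL)
      on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                             envir = globalenv()))
      set.seed(seed)
      f <- stats::fisher.test(tab, simulate.p.value = TRUE, B = B)
      list(test = "fisher_mc", statistic = NA_real_, p_value = f$p.value,
           untestable = FALSE)
    }
  }
}

#' Benjamini-Hochberg q-values
#'
#' Step-up false-discovery-rate adjustment with the running-minimum
#' monotonicity enforcement, applied within families.
#'
#' @param p numeric vector of p-values in [0, 1].
#' @param family optional grouping vector; adjustment is applied within each
#'   family separately (default: one family).
#' @return q-values, same length and order as `p`.
#' @export
adjust_fdr <- function(p, family = NULL) {
  stopifnot(all(p >= 0 & p <= 1, na.rm = TRUE))
  if (is.null(family)) return(stats::p.adjust(p, method = "BH"))
  q <- rep(NA_real_, length(p))
  for (f in unique(family)) {
    idx <- which(family == f)
    q[idx] <- stats::p.adjust(p[idx], method = "BH")
  }
  q
}

#' Class-covariate association battery
#'
#' Tests each fitted marker's MAP class assignment against each covariate
#' and adjusts p-values for false discovery. By default the FDR family is
#' per marker across covariates; set `family = "global"` to pool everything.
#'
#' @param models named list of `trajectory_fit` objects.
#' @param subjects subject table.
#' @param labs curated long lab table (for MAP assignment at day 21).
#' @param covariates named character vector mapping covariate column to kind
#'   (`"continuous"` or `"categorical"`).
#' @param family `"marker"` or `"global"` FDR family.
#' @param continuous_test passed to [test_association()].
#' @param seed seed for Monte-Carlo Fisher p-values.
#' @return data frame with `marker`, `covariate`, `test`, `statistic`,
#'   `p_value`, `q_value`, `significant` (q < 0.05).
#' @export
class_covariate_associations <- function(
    models, subjects, labs,
    covariates = c(age = "continuous", gender = "categorical",
                   ethnicity = "categorical", insurance = "categorical",
                   group = "categorical", length_of_stay = "continuous",
                   died_in_hospital = "categorical"),
    family = c("marker", "global"),
    continuous_test = "anova", seed = 1L) {
  family <- match.arg(family)
  rows <- list()
  for (m in names(models)) {
    series <- series_from_labs(labs, m, subjects = subjects$subject_id)
    pp <- posterior_probabilities(series, models[[m]], cutoff_day = 21)
    for (v in names(covariates)) {
      res <- test_association(pp$map_class, subjects[[v]],
                              kind = covariates[[v]],
                              continuous_test = continuous_test, seed = seed)
      rows[[paste(m, v)]] <- data.frame(
        marker = m, covariate = v, test = res$test,
        statistic = res$statistic, p_value = res$p_value,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  fam <- if (family == "marker") out$marker else rep("all", nrow(out))
  out$q_value <- adjust_fdr(out$p_value, fam)
  out$significant <- !is.na(out$q_value) & out$q_value < 0.05
  out
}

#' Heatmap of class-covariate association q-values
#'
#' Marker-by-covariate tile plot of -log10 q-values with significant cells
#' (q < 0.05) outlined.
#'
#' @param associations output of [class_covariate_associations()].
#' @return a ggplot object.
#' @export
plot_association_heatmap <- function(associations) {
  if (!requireNamespace("ggplot2", quietly = TRUE))
    stop("ggplot2 is required for plotting")
  d <- associations
  d$neglog_q <- -log10(pmax(d$q_value, 1e-16))
  ggplot2::ggplot(d, ggplot2::aes(x = covariate, y = marker,
                                  fill = neglog_q)) +
    ggplot2::geom_tile() +
    ggplot2::geom_tile(data = d[d$significant %in% TRUE, , drop = FALSE],
                       fill = NA, colour = "red", linewidth = 0.8) +
    ggplot2::scale_fill_gradient(low = "white", high = "steelblue",
                                 name = "-log10 q") +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_minimal()
}
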