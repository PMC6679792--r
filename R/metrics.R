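#' Mean absolute error
#'
#' @param predicted,actual Numeric vectors of equal length.
#' @return Mean of absolute differences.
#' @export
mae <- function(predicted, actual) {
  if (length(predicted) != length(actual)) {
    stop("predicted and actual differ in length")
  }
  mean(abs(predicted - actual))
}

#' 2-SD credible-interval coverage
#'
#' Fraction of cases where the true value falls within two standard
#' deviations of its estimate - the posterior (or predictive) credible
#' interval. Two exact SDs are used, so the nominal Gaussian level is
#' 95.45%, conventionally compared against 0.95.
#'
#' @param estimates,truths Numeric vectors of equal length.
#' @param sds Nonnegative SDs of the estimates.
#' @return An object of class `coverage_result`: list with `covered`
#'   (fraction in [0, 1]), `n`, and `nominal` (0.95).
#' @export
coverage <- function(estimates, sds, truths) {
  if (length(estimates) != length(sds) || length(estimates) != length(truths)) {
    stop("estimates, sds and truths must have equal length")
  }
  if (any(sds < 0)) stop("negative SD supplied")
  structure(list(covered = mean(abs(truths - estimates) <= 2 * sds),
                 n = length(estimates), nominal = 0.95),
            class = "coverage_result")
}

#' @export
print.coverage_result <- function(x, ...) {
  cat(sprintf("2-SD coverage: %.3f (n = %d, nominal %.2f)\n",
              x$covered, x$n, x$nominal))
  invisible(x)
}

#' Annualized rate of change
#'
#' The percentage change from baseline to final follow-up divided by the
#' number of elapsed years, in percent per year.
#'
#' @param pred_baseline Baseline value (nonzero).
#' @param pred_final Final follow-up value.
#' @param years Elapsed years (positive).
#' @return Rate in %/year.
#' @examples
#' annualized_rate(100, 90, 2)  # -5 %/yr
#' @export
annualized_rate <- function(pred_baseline, pred_final, years) {
  if (any(pred_baseline == 0)) stop("baseline value must be nonzero")
  if (any(years <= 0)) stop("elapsed years must be positive")
  100 * (pred_final - pred_baseline) / pred_baseline / years
}

#' One-way group-difference ANOVA with Bonferroni correction
#'
#' Classical one-way F test of group differences in point estimates (e.g.
#' per-subject slopes across diagnostic groups), with a caller-supplied
#' Bonferroni comparison count - the correction count depends on the full
#' testing family and is never inferred.
#'
#' @param values Numeric vector of point estimates.
#' @param labels Group labels (at least two groups, each with at least two
#'   members).
#' @param n_comparisons Number of comparisons in the Bonferroni family.
#' @return An object of class `group_test_result`: list with `statistic`
#'   (F), `df`, `p_raw`, `p_bonferroni = min(1, p_raw * n_comparisons)`,
#'   and `n_comparisons`.
#' @export
group_anova <- function(values, labels, n_comparisons = 1) {
  labels <- factor(labels)
  if (nlevels(labels) < 2) stop("need at least two groups")
  if (any(table(labels) < 2)) stop("every group needs at least two members")
  if (n_comparisons < 1) stop("n_comparisons must be at least 1")
  tab <- stats::anova(stats::lm(values ~ labels))
  p_raw <- tab[["Pr(>F)"]][1]
  structure(list(statistic = tab[["F value"]][1],
                 df = c(tab[["Df"]][1], tab[["Df"]][2]),
                 p_raw = p_raw,
                 p_bonferroni = min(1, p_raw * n_comparisons),
                 n_comparisons = as.integer(n_comparisons)),
            class = "group_test_result")
}

#' @export
print.group_test_result <- function(x, ...) {
  cat(sprintf("one-way ANOVA: F(%d, %d) = %.4g, p = %.3g (Bonferroni x%d: %.3g)\n",
              x$df[1], x$df[2], x$statistic, x$p_raw, x$n_comparisons,
              x$p_bonferroni))
  invisible(x)
}

#' Paired t test on absolute prediction errors
#'
#' Two-sided paired t test of the per-subject difference in absolute error
#' between two models. Identical error vectors (all differences zero) are
#' defined to give p = 1; a constant nonzero difference gives p = 0
#' (degenerate certainty).
#'
#' @param abs_err_a,abs_err_b Paired vectors of absolute errors.
#' @return List with `statistic` (t), `p_value`, and `n`.
#' @export
paired_abs_error_test <- function(abs_err_a, abs_err_b) {
  if (length(abs_err_a) != length(abs_err_b)) stop("error vectors differ in length")
  n <- length(abs_err_a)
  if (n < 2) stop("need at least two pairs")
  d <- abs(abs_err_a) - abs(abs_err_b)
  if (stats::sd(d) == 0) {
    return(list(statistic = if (mean(d) == 0) 0 else sign(mean(d)) * Inf,
                p_value = if (mean(d) == 0) 1 else 0, n = n))
  }
  tt <- stats::t.test(d)
  list(statistic = unname(tt$statistic), p_value = tt$p.value, n = n)
}

sample_skewness <- function(x) {
  z <- x - mean(x)
  mean(z^3) / mean(z^2)^1.5
}

sample_kurtosis <- function(x) {
  z <- x - mean(x)
  mean(z^4) / mean(z^2)^2 - 3
}

#' Residual diagnostics: normality moments and heteroscedasticity vs baseline age
#'
#' Summarizes fit residuals (skewness, excess kurtosis) and tests for
#' heteroscedasticity by correlating per-subject mean residuals with
#' baseline age (Pearson). Constant residuals make the correlation
#' undefined; it is then reported as 0 with `degenerate = TRUE`.
#'
#' @param residuals Numeric vector of per-observation residuals.
#' @param subjects Subject identifier per residual (same length).
#' @param baseline_ages Named or subject-ordered numeric vector of
#'   per-subject baseline ages.
#' @return List with `skewness`, `kurtosis`, `correlation`, `p_value`,
#'   `degenerate`, and `per_subject` (data.frame of subject, mean residual,
#'   baseline age).
#' @export
residual_diagnostics <- function(residuals, subjects, baseline_ages) {
  if (length(residuals) != length(subjects)) {
    stop("residuals and subjects differ in length")
  }
  if (length(residuals) < 3) stop("need at least three residuals")
  mean_resid <- tapply(residuals, as.character(subjects), mean)
  ids <- names(mean_resid)
  ages <- if (!is.null(names(baseline_ages))) baseline_ages[ids] else baseline_ages
  if (length(ages) != length(ids) || anyNA(ages)) {
    stop("baseline_ages must provide one age per subject")
  }
  per_subject <- data.frame(subject_id = ids,
                            mean_residual = as.numeric(mean_resid),
                            baseline_age = as.numeric(ages),
                            stringsAsFactors = FALSE)
  degenerate <- stats::sd(per_subject$mean_residual) == 0 ||
    stats::sd(per_subject$baseline_age) == 0
  if (degenerate) {
    correlation <- 0; p_value <- NA_real_
  } else {
    ct <- stats::cor.test(per_subject$mean_residual,
                          per_subject$baseline_age)
    correlation <- unname(ct$estimate); p_value <- ct$p.value
  }
  list(skewness = sample_skewness(residuals),
       kurtosis = sample_kurtosis(residuals),
       correlation = correlation, p_value = p_value,
       degenerate = degenerate, per_subject = per_subject)
}
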