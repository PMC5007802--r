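#' Agreement statistics between measured and predicted BMR
#'
#' Computes the validation battery for one equation on one cohort: bias
#' (mean of predicted minus measured, so a positive value is an
#' overestimation), SD of the differences, two-sided paired t-test, squared
#' Pearson correlation, Bland-Altman limits of agreement (bias +/- `loa_k`
#' SD of differences; the source definition uses exactly 2, not 1.96), and
#' the difference-versus-average regression used to detect directional bias.
#'
#' @param measured Measured BMR, kJ/d.
#' @param predicted Predicted BMR, kJ/d (same length, >= 3 pairs).
#' @param name Equation name carried into the report.
#' @param loa_k Multiplier on the SD of differences for the limits of
#'   agreement.
#' @return An object of class `bmr_agreement`: `equation`, `n`, `mean_meas`,
#'   `mean_pred`, `sd_pred`, `bias`, `sd_diff`, `p_paired_t`, `r2`,
#'   `loa_low`, `loa_high`, `ba_slope`, `ba_intercept`, `ba_r2`,
#'   `ba_slope_p`. Degenerate inputs (zero-variance differences or
#'   predictions) yield `NA` for the statistics that are undefined there.
#' @export
agreement_stats <- function(measured, predicted, name = "equation", loa_k = 2) {
  measured <- as.numeric(measured); predicted <- as.numeric(predicted)
  if (length(measured) != length(predicted)) {
    stop("measured and predicted must have equal length")
  }
  n <- length(measured)
  if (n < 3L) stop("need at least 3 pairs, got ", n)
  if (anyNA(measured) || anyNA(predicted)) stop("missing values in input")
  d <- predicted - measured
  avg <- (predicted + measured) / 2
  bias <- mean(d)
  sd_diff <- stats::sd(d)
  p_t <- if (sd_diff > 0) stats::t.test(predicted, measured,
                                        paired = TRUE)$p.value else NA_real_
  r2 <- if (stats::sd(measured) > 0 && stats::sd(predicted) > 0) {
    stats::cor(measured, predicted)^2
  } else if (all(predicted == measured)) 1 else NA_real_
  if (sd_diff > 0 && stats::sd(avg) > 0) {
    ba <- stats::lm(d ~ avg)
    # degenerate fixtures can make d ~ avg an exact fit; the summary is
    # still the right report, so silence the perfect-fit warning
    sm <- suppressWarnings(summary(ba))
    ba_slope <- unname(stats::coef(ba)[2])
    ba_intercept <- unname(stats::coef(ba)[1])
    ba_r2 <- sm$r.squared
    ba_slope_p <- sm$coefficients[2, 4]
  } else {
    ba_slope <- if (sd_diff == 0) 0 else NA_real_
    ba_intercept <- bias
    ba_r2 <- NA_real_
    ba_slope_p <- NA_real_
  }
  structure(list(
    equation = name, n = n,
    mean_meas = mean(measured), mean_pred = mean(predicted),
    sd_pred = stats::sd(predicted),
    bias = bias, sd_diff = sd_diff, p_paired_t = p_t, r2 = r2,
    loa_low = bias - loa_k * sd_diff, loa_high = bias + loa_k * sd_diff,
    ba_slope = ba_slope, ba_intercept = ba_intercept,
    ba_r2 = ba_r2, ba_slope_p = ba_slope_p
  ), class = "bmr_agreement")
}

#' @export
print.bmr_agreement <- function(x, ...) {
  cat(sprintf("Agreement report: %s (n = %d)\n", x$equation, x$n))
  cat(sprintf("  predicted %.0f +/- %.0f kJ/d, bias %.0f +/- %.0f kJ/d\n",
              x$mean_pred, x$sd_pred, x$bias, x$sd_diff))
  cat(sprintf("  paired t p = %s, R^2 = %.2f\n",
              format.pval(x$p_paired_t, digits = 2), x$r2))
  cat(sprintf("  limits of agreement: %.0f to %.0f kJ/d\n",
              x$loa_low, x$loa_high))
  cat(sprintf("  difference vs average: slope %.3f (p = %s, R^2 = %.2f)\n",
              x$ba_slope, format.pval(x$ba_slope_p, digits = 2), x$ba_r2))
  invisible(x)
}

#' Classify predictions as under-, accurately or over-estimated
#'
#' A prediction is accurate when it lies within +/-10 percent of the
#' measured value (boundary inclusive); above +10 percent it is an
#' overestimate, below -10 percent an underestimate.
#'
#' @param measured Measured BMR, kJ/d (> 0).
#' @param predicted Predicted BMR, kJ/d.
#' @param tol Relative tolerance (fraction of measured).
#' @return Factor with levels `under`, `accurate`, `over`.
#' @examples
#' accuracy_classify(6000, c(5399, 5400, 6600, 6601))
#' @export
accuracy_classify <- function(measured, predicted, tol = 0.10) {
  if (any(!is.finite(measured) | measured <= 0)) {
    stop("measured BMR must be > 0")
  }
  rel <- (predicted - measured) / measured
  factor(ifelse(rel < -tol, "under", ifelse(rel > tol, "over", "accurate")),
         levels = c("under", "accurate", "over"))
}

accuracy_pcts <- function(cls) {
  n <- length(cls)
  if (n == 0L) {
    return(data.frame(n = 0L, pct_under = NA_real_, pct_accurate = NA_real_,
                      pct_over = NA_real_))
  }
  tab <- table(cls) / n * 100
  data.frame(n = n, pct_under = unname(tab["under"]),
             pct_accurate = unname(tab["accurate"]),
             pct_over = unname(tab["over"]))
}

#' BMI-stratified accuracy breakdown for one equation
#'
#' Percentages of under-, accurately and over-estimated subjects overall and
#' within the two BMI strata (at or below the cut vs above it; boundary in
#' the lower stratum). Percentages are kept at full precision; the print
#' method rounds to whole percent as the tables are conventionally shown.
#'
#' @param cohort Subject data frame with measured BMR.
#' @param eq A [prediction_equation()].
#' @param bmi_cut BMI stratification cut, kg/m^2.
#' @param tol Accuracy tolerance (fraction of measured BMR).
#' @param policy What to do with subjects outside the equation's age bands:
#'   `"skip"` drops them (count reported), `"fail"` raises the dispatch
#'   error.
#' @return An object of class `bmr_accuracy`: data frame with one row per
#'   stratum (`all`, `<=cut`, `>cut`) and columns `n`, `pct_under`,
#'   `pct_accurate`, `pct_over`; empty strata carry `NA` percentages.
#'   Attributes `equation` and `n_skipped`.
#' @export
accuracy_breakdown <- function(cohort, eq, bmi_cut = 23.0, tol = 0.10,
                               policy = c("skip", "fail")) {
  policy <- match.arg(policy)
  cohort <- validate_subjects(cohort, require_bmr = TRUE)
  n_skipped <- 0L
  if (policy == "skip") {
    ok <- has_band(eq, cohort$sex, cohort$age)
    n_skipped <- sum(!ok)
    cohort <- cohort[ok, , drop = FALSE]
  }
  if (nrow(cohort) == 0L) {
    out <- data.frame(stratum = c("all", paste0("<=", bmi_cut),
                                  paste0(">", bmi_cut)),
                      n = 0L, pct_under = NA_real_, pct_accurate = NA_real_,
                      pct_over = NA_real_)
  } else {
    pred <- predict_bmr(eq, cohort)
    cls <- accuracy_classify(cohort$bmr_measured, pred, tol = tol)
    strat <- bmi_stratum(compute_bmi(cohort$weight, cohort$height),
                         cut = bmi_cut)
    rows <- list(all = accuracy_pcts(cls))
    for (lv in levels(strat)) rows[[lv]] <- accuracy_pcts(cls[strat == lv])
    out <- cbind(stratum = names(rows), do.call(rbind, rows))
    rownames(out) <- NULL
  }
  structure(out, equation = eq$name, n_skipped = n_skipped,
            class = c("bmr_accuracy", "data.frame"))
}

#' @export
print.bmr_accuracy <- function(x, ...) {
  cat(sprintf("Accuracy breakdown: %s%s\n", attr(x, "equation"),
              if (attr(x, "n_skipped") > 0)
                sprintf(" (%d subject(s) outside age bands skipped)",
                        attr(x, "n_skipped")) else ""))
  y <- as.data.frame(x)
  for (col in c("pct_under", "pct_accurate", "pct_over")) {
    y[[col]] <- ifelse(is.na(y[[col]]), "-", paste0(round(y[[col]]), "%"))
  }
  print(y, row.names = FALSE)
  invisible(x)
}

#' Evaluate a registry of equations on a cohort
#'
#' Runs [agreement_stats()] and [accuracy_breakdown()] for every equation
#' and ranks the equations by overall accuracy rate (descending), ties
#' broken by absolute bias (ascending).
#'
#' @param cohort Subject data frame with measured BMR.
#' @param eqs List of [prediction_equation()]s (default: the built-in
#'   registry).
#' @param bmi_cut BMI stratification cut, kg/m^2.
#' @param loa_k Limits-of-agreement multiplier.
#' @param tol Accuracy tolerance.
#' @param policy Band-dispatch policy, as in [accuracy_breakdown()]; an
#'   equation left with fewer than 3 evaluable subjects is reported with
#'   `NA` statistics.
#' @return An object of class `bmr_evaluation`: list with `table` (ranked
#'   summary data frame), `reports` (named list of `bmr_agreement`) and
#'   `accuracy` (named list of `bmr_accuracy`).
#' @export
evaluate_equations <- function(cohort, eqs = builtin_equations(),
                               bmi_cut = 23.0, loa_k = 2, tol = 0.10,
                               policy = c("skip", "fail")) {
  policy <- match.arg(policy)
  cohort <- validate_subjects(cohort, require_bmr = TRUE)
  if (nrow(cohort) == 0L) stop("empty cohort")
  if (length(eqs) == 0L) stop("empty equation registry")
  if (inherits(eqs, "bmr_equation")) eqs <- list(eqs)
  nm <- vapply(eqs, function(e) e$name, character(1))
  names(eqs) <- nm

  reports <- list(); accuracy <- list(); rows <- list()
  for (e in eqs) {
    sub <- cohort
    n_skipped <- 0L
    if (policy == "skip") {
      ok <- has_band(e, sub$sex, sub$age)
      n_skipped <- sum(!ok)
      sub <- sub[ok, , drop = FALSE]
    }
    acc <- accuracy_breakdown(sub, e, bmi_cut = bmi_cut, tol = tol,
                              policy = policy)
    rep <- if (nrow(sub) >= 3L) {
      agreement_stats(sub$bmr_measured, predict_bmr(e, sub),
                      name = e$name, loa_k = loa_k)
    } else NULL
    reports[[e$name]] <- rep
    accuracy[[e$name]] <- acc
    num <- function(v) if (is.null(v)) NA_real_ else v
    a <- as.data.frame(acc)
    rows[[e$name]] <- data.frame(
      equation = e$name, n = nrow(sub), n_skipped = n_skipped,
      mean_pred = num(rep$mean_pred), sd_pred = num(rep$sd_pred),
      bias = num(rep$bias), sd_diff = num(rep$sd_diff),
      p_paired_t = num(rep$p_paired_t), r2 = num(rep$r2),
      loa_low = num(rep$loa_low), loa_high = num(rep$loa_high),
      ba_slope = num(rep$ba_slope), ba_slope_p = num(rep$ba_slope_p),
      pct_under_all = a$pct_under[a$stratum == "all"],
      pct_accurate_all = a$pct_accurate[a$stratum == "all"],
      pct_over_all = a$pct_over[a$stratum == "all"],
      pct_under_low = a$pct_under[2], pct_accurate_low = a$pct_accurate[2],
      pct_over_low = a$pct_over[2],
      pct_under_high = a$pct_under[3], pct_accurate_high = a$pct_accurate[3],
      pct_over_high = a$pct_over[3]
    )
  }
  tab <- do.call(rbind, rows)
  ord <- order(-ifelse(is.na(tab$pct_accurate_all), -Inf,
                       tab$pct_accurate_all),
               ifelse(is.na(tab$bias), Inf, abs(tab$bias)))
  tab <- tab[ord, , drop = FALSE]
  rownames(tab) <- NULL
  structure(list(table = tab, reports = reports, accuracy = accuracy,
                 bmi_cut = bmi_cut, loa_k = loa_k, tol = tol),
            class = "bmr_evaluation")
}

#' @export
print.bmr_evaluation <- function(x, ...) {
  cat(sprintf(
    "Equation evaluation (n = %d, ranked by accuracy within +/-%.0f%%)\n",
    max(x$table$n), x$tol * 100))
  t <- x$table
  show <- data.frame(
    equation = t$equation,
    `pred kJ/d` = sprintf("%.0f +/- %.0f", t$mean_pred, t$sd_pred),
    `bias kJ/d` = sprintf("%.0f +/- %.0f", t$bias, t$sd_diff),
    `R2` = sprintf("%.2f", t$r2),
    LoA = sprintf("%.0f to %.0f", t$loa_low, t$loa_high),
    `under/acc/over %` = sprintf("%.0f/%.0f/%.0f", t$pct_under_all,
                                 t$pct_accurate_all, t$pct_over_all),
    check.names = FALSE
  )
  print(show, row.names = FALSE)
  invisible(x)
}

#' Bland-Altman plot for one equation
#'
#' Plots predicted-minus-measured differences against the pairwise averages
#' with the bias, the limits of agreement and the difference-versus-average
#' regression line. Requires ggplot2.
#'
#' @param measured,predicted BMR vectors, kJ/d.
#' @param name Equation name for the title.
#' @param loa_k Limits-of-agreement multiplier.
#' @return A ggplot object.
#' @export
plot_bland_altman <- function(measured, predicted, name = "equation",
                              loa_k = 2) {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop("plot_bland_altman requires the ggplot2 package")
  }
  st <- agreement_stats(measured, predicted, name = name, loa_k = loa_k)
  df <- data.frame(avg = (measured + predicted) / 2,
                   diff = predicted - measured)
  ggplot2::ggplot(df, ggplot2::aes(x = avg, y = diff)) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::geom_hline(yintercept = st$bias, linetype = "dotted") +
    ggplot2::geom_hline(yintercept = c(st$loa_low, st$loa_high)) +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE,
                         linewidth = 0.5, colour = "grey40") +
    ggplot2::labs(
      title = name,
      subtitle = sprintf("bias %.0f kJ/d, LoA %.0f to %.0f, slope %.3f (p = %.3g)",
                         st$bias, st$loa_low, st$loa_high, st$ba_slope,
                         st$ba_slope_p),
      x = "Average of measured and predicted BMR (kJ/d)",
      y = "Predicted - measured BMR (kJ/d)"
    )
}
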