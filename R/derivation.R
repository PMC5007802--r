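#' Ordinary least squares with the goodness-of-fit measures used for
#' BMR equation derivation
#'
#' Fits `y ~ X` with an intercept and reports the coefficient of
#' determination R^2 and the residual standard deviation
#' RD = sqrt(SSE / (n - k - 1)), the two statistics used to judge candidate
#' BMR equations (k = number of covariates).
#'
#' @param y Response vector (measured BMR, kJ/d).
#' @param X Covariate data frame or matrix (may have zero columns for an
#'   intercept-only fit).
#' @return An object of class `bmr_fit`: list with `included` (covariate
#'   names in model order), `coefficients` (named, intercept first), `r2`,
#'   `rd` (kJ/d), `n`, `residuals`, `fitted`, and `step_trace` (`NULL` here;
#'   filled by [stepwise_derive()]).
#' @export
fit_ols <- function(y, X) {
  y <- as.numeric(y)
  X <- as.data.frame(X)
  n <- length(y)
  k <- ncol(X)
  if (nrow(X) != n && k > 0L) stop("y and X must have matching rows")
  if (n <= k + 1L) stop("need n > number of covariates + 1 (n = ", n,
                        ", covariates = ", k, ")")
  if (anyNA(y) || (k > 0L && anyNA(X))) stop("missing values in y or X")
  dat <- cbind(data.frame(.y = y), X)
  fit <- if (k == 0L) stats::lm(.y ~ 1, data = dat) else
    stats::lm(.y ~ ., data = dat)
  if (anyNA(stats::coef(fit))) {
    bad <- names(stats::coef(fit))[is.na(stats::coef(fit))]
    stop("covariate matrix is rank deficient; collinear column(s): ",
         paste(bad, collapse = ", "))
  }
  res <- stats::residuals(fit)
  sse <- sum(res^2)
  sst <- sum((y - mean(y))^2)
  structure(list(
    included = colnames(X),
    coefficients = stats::coef(fit),
    r2 = if (sst > 0) 1 - sse / sst else NA_real_,
    rd = sqrt(sse / (n - k - 1L)),
    n = n,
    residuals = res,
    fitted = stats::fitted(fit),
    step_trace = NULL
  ), class = "bmr_fit")
}

#' @export
print.bmr_fit <- function(x, ...) {
  cat("BMR regression fit (n =", x$n, ")\n")
  cat("  covariates:", if (length(x$included)) paste(x$included, collapse = ", ")
      else "(intercept only)", "\n")
  co <- signif(x$coefficients, 6)
  cat("  coefficients:", paste(names(co), "=", co, collapse = ", "), "\n")
  cat(sprintf("  R^2 = %.4f, RD = %.1f kJ/d\n", x$r2, x$rd))
  if (!is.null(x$step_trace)) {
    cat("  stepwise trace:\n")
    tr <- x$step_trace
    for (i in seq_len(nrow(tr))) {
      cat(sprintf("    %s %-8s RD = %6.1f  p = %.3g\n",
                  if (tr$action[i] == "add") "+" else "-",
                  tr$term[i], tr$rd[i], tr$p_value[i]))
    }
  }
  invisible(x)
}

# Covariate design matrix for derivation: weight (kg), height (cm),
# age (years), gender (men = 1, women = 0).
derivation_covariates <- function(cohort) {
  data.frame(weight = cohort$weight, height = cohort$height,
             age = cohort$age, gender = sex_indicator(cohort$sex))
}

#' Derive a BMR prediction equation by forward stepwise regression
#'
#' Reproduces the derivation procedure: starting from the intercept-only
#' model, at each step the candidate covariate giving the largest reduction
#' in residual standard deviation (RD) whose partial-F p-value is below the
#' entry threshold is added; selection stops when no candidate qualifies.
#' With `direction = "both"`, after each addition any included covariate
#' whose partial-F p-value has risen above `remove_p` is dropped again.
#'
#' @param cohort Subject data frame with measured BMR for every subject and
#'   both sexes present when `"gender"` is a candidate.
#' @param candidates Candidate covariates, a subset of
#'   `c("weight", "height", "age", "gender")`. Empty gives the
#'   intercept-only fit (RD = sample SD of the response).
#' @param entry_p Partial-F p-value required for entry.
#' @param direction `"forward"` (default) or `"both"` (allow removal).
#' @param remove_p Partial-F p-value above which a term is removed
#'   (`direction = "both"` only).
#' @return A `bmr_fit` whose `step_trace` records, per step, the term,
#'   action, RD after the step and the partial-F p-value.
#' @seealso [render_equation()] to fold the gender term into per-sex
#'   intercepts.
#' @export
stepwise_derive <- function(cohort,
                            candidates = c("weight", "height", "age", "gender"),
                            entry_p = 0.05,
                            direction = c("forward", "both"),
                            remove_p = 0.10) {
  direction <- match.arg(direction)
  cohort <- validate_subjects(cohort, require_bmr = TRUE)
  if (nrow(cohort) == 0L) stop("empty cohort")
  if (length(candidates)) {
    candidates <- sort(unique(match.arg(candidates,
      c("weight", "height", "age", "gender"), several.ok = TRUE)))
  } else {
    candidates <- character(0)
  }
  if ("gender" %in% candidates && length(unique(cohort$sex)) < 2L) {
    stop("gender cannot be a candidate in a single-sex cohort")
  }
  y <- cohort$bmr_measured
  Xall <- derivation_covariates(cohort)

  included <- character(0)
  trace <- data.frame(term = character(0), action = character(0),
                      rd = numeric(0), p_value = numeric(0))
  lm_terms <- function(terms) {
    dat <- cbind(data.frame(y = y), Xall[terms])
    stats::lm(if (length(terms)) y ~ . else y ~ 1, data = dat)
  }
  partial_p <- function(with_terms, term) {
    # partial F test for `term` on top of the other terms in `with_terms`
    stats::anova(lm_terms(setdiff(with_terms, term)),
                 lm_terms(with_terms))[2, "Pr(>F)"]
  }
  rd_of <- function(terms) fit_ols(y, Xall[terms])$rd

  repeat {
    remaining <- setdiff(candidates, included)
    if (!length(remaining)) break
    rds <- vapply(remaining, function(tm) rd_of(c(included, tm)), numeric(1))
    ps <- vapply(remaining, function(tm) partial_p(c(included, tm), tm),
                 numeric(1))
    ok <- is.finite(ps) & ps < entry_p
    if (!any(ok)) break
    # largest RD reduction among qualifying; ties by alphabetical order,
    # which `remaining` already has (candidates are sorted)
    pick <- remaining[ok][which.min(rds[ok])]
    included <- c(included, pick)
    trace <- rbind(trace, data.frame(term = pick, action = "add",
                                     rd = rds[names(rds) == pick][1],
                                     p_value = ps[names(ps) == pick][1]))
    if (direction == "both" && length(included) > 1L) {
      repeat {
        drop_p <- vapply(setdiff(included, pick),
                         function(tm) partial_p(included, tm), numeric(1))
        if (!length(drop_p) || all(drop_p <= remove_p)) break
        worst <- names(drop_p)[which.max(drop_p)]
        included <- setdiff(included, worst)
        trace <- rbind(trace, data.frame(term = worst, action = "remove",
                                         rd = rd_of(included),
                                         p_value = max(drop_p)))
      }
    }
  }
  fit <- fit_ols(y, Xall[included])
  fit$step_trace <- trace
  fit
}

#' Render a regression fit as a per-sex prediction equation
#'
#' Folds the gender indicator (men = 1, women = 0) into per-sex intercepts,
#' producing a two-row adult prediction equation in the registry format:
#' the men's intercept is the fitted intercept plus the gender coefficient.
#' Rendered coefficients are rounded registry-style: slopes to `digits`
#' (default 3) significant figures and intercepts to one more, the precision
#' the published equations carry; pass `digits = NULL` to keep full
#' precision.
#'
#' @param fit A `bmr_fit` from [fit_ols()] or [stepwise_derive()] whose
#'   covariates are among weight, height, age, gender.
#' @param name Name for the rendered equation.
#' @param digits Significant digits for the rendered slope coefficients;
#'   intercepts get `digits + 1` (`NULL` = no rounding).
#' @return A [prediction_equation()] with one adult band per sex.
#' @export
render_equation <- function(fit, name = "Derived", digits = 3) {
  stopifnot(inherits(fit, "bmr_fit"))
  extra <- setdiff(fit$included, c("weight", "height", "age", "gender"))
  if (length(extra)) {
    stop("cannot render covariate(s) ", paste(extra, collapse = ", "),
         " as a weight/height/age/gender equation")
  }
  co <- function(term) {
    v <- unname(fit$coefficients[term])
    if (is.na(v)) 0 else v
  }
  g <- if ("gender" %in% fit$included) unname(fit$coefficients["gender"]) else 0
  intercept <- unname(fit$coefficients["(Intercept)"])
  vals <- c(m_int = intercept + g, f_int = intercept,
            w = co("weight"), h = co("height"), a = co("age"))
  if (!is.null(digits)) {
    vals[c("w", "h", "a")] <- signif(vals[c("w", "h", "a")], digits)
    vals[c("m_int", "f_int")] <- signif(vals[c("m_int", "f_int")], digits + 1)
  }
  prediction_equation(name, adult_bands(
    m_int = vals["m_int"], m_w = vals["w"], m_h = vals["h"], m_a = vals["a"],
    f_int = vals["f_int"], f_w = vals["w"], f_h = vals["h"], f_a = vals["a"]))
}
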