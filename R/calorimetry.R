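#' Construct a gas-exchange series
#'
#' Holds an ordered ventilated-hood time series of oxygen consumption and
#' carbon dioxide production sampled at a uniform interval (5 s in the
#' measurement protocol). Time is seconds from session start, first sample
#' at t = 0.
#'
#' @param t Sample times, seconds; strictly increasing and uniformly spaced.
#' @param vo2 Oxygen consumption, L/min (STPD), >= 0.
#' @param vco2 Carbon dioxide production, L/min (STPD), >= 0.
#' @param interval Sampling interval in seconds; inferred from `t` when `NULL`.
#' @param tolerance Relative tolerance on spacing uniformity.
#' @return A data frame of class `gas_series` with columns `t`, `vo2`,
#'   `vco2` and an `interval` attribute.
#' @export
gas_series <- function(t, vo2, vco2, interval = NULL, tolerance = 1e-6) {
  stopifnot(length(t) == length(vo2), length(t) == length(vco2))
  if (length(t) == 0L) stop("empty gas-exchange series")
  t <- as.numeric(t); vo2 <- as.numeric(vo2); vco2 <- as.numeric(vco2)
  if (any(!is.finite(vo2) | vo2 < 0) || any(!is.finite(vco2) | vco2 < 0)) {
    stop("vo2 and vco2 must be finite and >= 0")
  }
  if (length(t) > 1L) {
    dt <- diff(t)
    if (any(dt <= 0)) stop("sample times must be strictly increasing")
    if (is.null(interval)) interval <- dt[1L]
    if (any(abs(dt - interval) > tolerance * interval)) {
      stop("sample times are not uniformly spaced at ", interval, " s")
    }
  } else if (is.null(interval)) {
    interval <- 5
  }
  structure(data.frame(t = t, vo2 = vo2, vco2 = vco2),
            interval = interval, class = c("gas_series", "data.frame"))
}

#' @export
print.gas_series <- function(x, ...) {
  cat(sprintf("Gas-exchange series: %d samples at %g s (%.1f min)\n",
              nrow(x), attr(x, "interval"),
              (nrow(x) * attr(x, "interval")) / 60))
  cat(sprintf("  VO2  %.4f-%.4f L/min, VCO2 %.4f-%.4f L/min\n",
              min(x$vo2), max(x$vo2), min(x$vco2), max(x$vco2)))
  invisible(x)
}

# Abbreviated Weir constants (kcal per litre of gas) and unit conversions.
WEIR_O2 <- 3.941
WEIR_CO2 <- 1.106
MIN_PER_DAY <- 1440
KJ_PER_KCAL <- 4.184

#' Energy expenditure from gas exchange (abbreviated Weir formula)
#'
#' Converts oxygen consumption and carbon dioxide production rates into
#' energy expenditure using the abbreviated Weir formula without urinary
#' nitrogen correction (the standard form for ventilated-hood measurements,
#' where urine is not collected):
#' `(3.941 VO2 + 1.106 VCO2) kcal/min * 1440 min/d * 4.184 kJ/kcal`.
#'
#' @param vo2 Oxygen consumption, L/min (>= 0).
#' @param vco2 Carbon dioxide production, L/min (>= 0).
#' @return Energy expenditure in kJ/d.
#' @examples
#' weir_bmr(0.25, 0.20)  # 7268.8 kJ/d
#' @export
weir_bmr <- function(vo2, vco2) {
  if (any(!is.finite(vo2) | vo2 < 0) || any(!is.finite(vco2) | vco2 < 0)) {
    stop("vo2 and vco2 must be finite and >= 0")
  }
  (WEIR_O2 * vo2 + WEIR_CO2 * vco2) * MIN_PER_DAY * KJ_PER_KCAL
}

#' Discard the habituation period
#'
#' Subjects take several minutes to habituate to the hood, so the first part
#' of the recording (5 min in the protocol) is discarded before any
#' steady-state analysis.
#'
#' @param series A [gas_series()].
#' @param discard Seconds to discard from the start of the session.
#' @return The suffix of the series with `t >= discard`.
#' @export
discard_habituation <- function(series, discard = 300) {
  stopifnot(inherits(series, "gas_series"), discard >= 0)
  duration <- nrow(series) * attr(series, "interval")
  if (duration <= discard) {
    stop("series duration (", duration, " s) must exceed the discard period (",
         discard, " s)")
  }
  keep <- series$t >= discard
  gas_series(series$t[keep], series$vo2[keep], series$vco2[keep],
             interval = attr(series, "interval"))
}

#' Select the best steady-state window
#'
#' Scans every sliding window of the given length (step = sampling interval;
#' windows are half-open `[start, start + window)`) and computes the
#' coefficient of variation (CV = SD/mean) of VO2 and VCO2 within each.
#' Among windows with both CVs at or below `cv_max`, the window minimising
#' `cv_vo2 + cv_vco2` is returned; ties are broken by earliest start. Apply
#' [discard_habituation()] first so the window lies after the habituation
#' period.
#'
#' @param series A [gas_series()] (post-discard).
#' @param window Window length, seconds; must be a multiple of the interval.
#' @param cv_max Maximum admissible CV for each gas (fraction).
#' @return A list of class `steady_window` with `start`, `end` (seconds),
#'   `cv_vo2`, `cv_vco2`, `mean_vo2`, `mean_vco2` and `n` samples.
#' @export
select_steady_state <- function(series, window = 600, cv_max = 0.10) {
  stopifnot(inherits(series, "gas_series"))
  interval <- attr(series, "interval")
  nw <- window / interval
  if (abs(nw - round(nw)) > 1e-9 || nw < 2) {
    stop("window must be a multiple of the sampling interval spanning >= 2 samples")
  }
  nw <- as.integer(round(nw))
  n <- nrow(series)
  if (n < nw) {
    stop("series has ", n, " samples but the window needs ", nw)
  }
  starts <- seq_len(n - nw + 1L)
  win_cv <- function(x, i) {
    v <- x[i:(i + nw - 1L)]
    m <- mean(v)
    if (m <= 0) return(Inf)
    stats::sd(v) / m
  }
  cv1 <- vapply(starts, function(i) win_cv(series$vo2, i), numeric(1))
  cv2 <- vapply(starts, function(i) win_cv(series$vco2, i), numeric(1))
  total <- cv1 + cv2
  ok <- cv1 <= cv_max & cv2 <= cv_max
  pick_from <- if (any(ok)) which(ok) else seq_along(starts)
  best <- pick_from[which.min(total[pick_from])]  # which.min takes the earliest tie
  i <- starts[best]
  out <- structure(list(
    start = series$t[i], end = series$t[i] + window,
    cv_vo2 = cv1[best], cv_vco2 = cv2[best],
    mean_vo2 = mean(series$vo2[i:(i + nw - 1L)]),
    mean_vco2 = mean(series$vco2[i:(i + nw - 1L)]),
    n = nw
  ), class = "steady_window")
  if (!any(ok)) {
    stop(structure(class = c("bmrkit_no_steady_state", "error", "condition"),
      list(message = sprintf(
        paste0("no steady-state window found: best window [%g, %g) s has ",
               "CV(VO2) = %.4f, CV(VCO2) = %.4f (limit %.4f)"),
        out$start, out$end, out$cv_vo2, out$cv_vco2, cv_max),
        call = NULL, best = out)))
  }
  out
}

#' @export
print.steady_window <- function(x, ...) {
  cat(sprintf(
    "Steady-state window [%g, %g) s: CV(VO2) = %.3f, CV(VCO2) = %.3f\n",
    x$start, x$end, x$cv_vo2, x$cv_vco2))
  cat(sprintf("  mean VO2 = %.4f L/min, mean VCO2 = %.4f L/min (%d samples)\n",
              x$mean_vo2, x$mean_vco2, x$n))
  invisible(x)
}

#' Measured BMR from a ventilated-hood session
#'
#' Full processing chain for one 30-min recording: discard the habituation
#' period, select the best steady-state window, and feed the window means of
#' VO2 and VCO2 to [weir_bmr()].
#'
#' @param series A [gas_series()] for the whole session.
#' @param discard Habituation discard, seconds.
#' @param window Steady-state window length, seconds.
#' @param cv_max Maximum admissible CV per gas.
#' @param all_windows If `TRUE`, average the Weir BMR over every qualifying
#'   window instead of using only the best one. Off by default: the standard
#'   protocol reports a single steady-state value per session.
#' @return A list with `bmr` (kJ/d) and `window` (the selected
#'   [select_steady_state()] result; for `all_windows = TRUE`, the best one).
#' @export
series_to_bmr <- function(series, discard = 300, window = 600, cv_max = 0.10,
                          all_windows = FALSE) {
  trimmed <- discard_habituation(series, discard)
  best <- select_steady_state(trimmed, window = window, cv_max = cv_max)
  if (!all_windows) {
    return(list(bmr = weir_bmr(best$mean_vo2, best$mean_vco2), window = best))
  }
  interval <- attr(trimmed, "interval")
  nw <- as.integer(round(window / interval))
  starts <- seq_len(nrow(trimmed) - nw + 1L)
  bmrs <- vapply(starts, function(i) {
    v1 <- trimmed$vo2[i:(i + nw - 1L)]; v2 <- trimmed$vco2[i:(i + nw - 1L)]
    ok <- mean(v1) > 0 && mean(v2) > 0 &&
      stats::sd(v1) / mean(v1) <= cv_max && stats::sd(v2) / mean(v2) <= cv_max
    if (ok) weir_bmr(mean(v1), mean(v2)) else NA_real_
  }, numeric(1))
  list(bmr = mean(bmrs, na.rm = TRUE), window = best)
}
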