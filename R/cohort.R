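#' Cohort generator specification
#'
#' Describes a synthetic study population: per-sex sample sizes and
#' weight/height/age moments, the linear mean structure of measured BMR
#' (intercept + weight coefficient * weight + gender coefficient * indicator,
#' men = 1), and a homoscedastic Normal residual SD. The presets reproduce
#' the two study populations the package's validation battery is calibrated
#' against:
#'
#' * `"cross_sectional"` - 121 men and 111 women; men 79.2 +/- 14.9 kg,
#'   171.7 +/- 5.9 cm, 32.3 +/- 9.9 y; women 66.1 +/- 16.1 kg,
#'   159.9 +/- 6.2 cm, 33.4 +/- 11.2 y; BMR mean structure
#'   `52.6 W + 828 G + 1960` kJ/d with residual SD 534 kJ/d.
#' * `"cross_validation"` - 26 men and 44 women; men 72.1 +/- 13.3 kg,
#'   173.4 +/- 6.3 cm, 28.2 +/- 6.3 y; women 59.7 +/- 15.6 kg,
#'   162.3 +/- 5.3 cm, 28.8 +/- 10.2 y; same mean structure and residual SD.
#'
#' Covariates are sampled from untruncated Normals by default and weight,
#' height and age are independent within sex (`wh_corr = 0`); an optional
#' weight-height correlation and rejection truncation against the preset's
#' observed ranges are available for added realism (see the methods
#' vignette for why the defaults are the untruncated, independent model).
#'
#' @param preset `"cross_sectional"` or `"cross_validation"`.
#' @param n_men,n_women Sample sizes (fixed counts, not Bernoulli draws).
#' @param men,women Per-sex moment lists, each
#'   `list(weight = c(mean, sd), height = c(mean, sd), age = c(mean, sd))`
#'   (kg, cm, years).
#' @param true_coeffs Named vector `c(intercept, weight, gender)` of the BMR
#'   mean structure, kJ/d (per kg for `weight`).
#' @param residual_sd Residual SD of measured BMR about the mean structure,
#'   kJ/d.
#' @param wh_corr Within-sex correlation between weight and height.
#' @param truncate If `TRUE`, covariates are rejection-sampled against
#'   `ranges`.
#' @param ranges `list(weight = c(min, max), height = ..., age = ...)` used
#'   when `truncate = TRUE`; presets carry the observed study ranges.
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(preset = c("cross_sectional", "cross_validation"),
                        n_men = NULL, n_women = NULL,
                        men = NULL, women = NULL,
                        true_coeffs = c(intercept = 1960, weight = 52.6,
                                        gender = 828),
                        residual_sd = 534,
                        wh_corr = 0,
                        truncate = FALSE,
                        ranges = NULL) {
  preset <- match.arg(preset)
  presets <- list(
    cross_sectional = list(
      n_men = 121L, n_women = 111L,
      men = list(weight = c(79.2, 14.9), height = c(171.7, 5.9),
                 age = c(32.3, 9.9)),
      women = list(weight = c(66.1, 16.1), height = c(159.9, 6.2),
                   age = c(33.4, 11.2)),
      ranges = list(weight = c(39.3, 113.1), height = c(147.4, 189.3),
                    age = c(21.6, 66.8))),
    cross_validation = list(
      n_men = 26L, n_women = 44L,
      men = list(weight = c(72.1, 13.3), height = c(173.4, 6.3),
                 age = c(28.2, 6.3)),
      women = list(weight = c(59.7, 15.6), height = c(162.3, 5.3),
                   age = c(28.8, 10.2)),
      ranges = list(weight = c(40.7, 104.6), height = c(151.9, 185.5),
                    age = c(21.6, 66.8)))
  )
  p <- presets[[preset]]
  spec <- list(
    preset = preset,
    n_men = if (is.null(n_men)) p$n_men else as.integer(n_men),
    n_women = if (is.null(n_women)) p$n_women else as.integer(n_women),
    men = if (is.null(men)) p$men else men,
    women = if (is.null(women)) p$women else women,
    true_coeffs = true_coeffs,
    residual_sd = residual_sd,
    wh_corr = wh_corr,
    truncate = truncate,
    ranges = if (is.null(ranges)) p$ranges else ranges
  )
  stopifnot(spec$n_men >= 0L, spec$n_women >= 0L,
            spec$n_men + spec$n_women > 0L,
            all(c("intercept", "weight", "gender") %in% names(true_coeffs)),
            residual_sd >= 0, abs(wh_corr) < 1)
  for (side in c("men", "women")) {
    for (v in c("weight", "height", "age")) {
      mv <- spec[[side]][[v]]
      if (length(mv) != 2L || !all(is.finite(mv)) || mv[2] <= 0) {
        stop(side, "$", v, " must be c(mean, sd) with sd > 0")
      }
      if (spec$truncate) {
        r <- spec$ranges[[v]]
        if (length(r) != 2L || r[1] >= r[2]) {
          stop("ranges$", v, " must be c(min, max) with min < max")
        }
        if (r[2] < mv[1] - 6 * mv[2] || r[1] > mv[1] + 6 * mv[2]) {
          stop("infeasible truncation for ", side, "$", v,
               ": range excludes mean +/- 6 SD")
        }
      }
    }
  }
  structure(spec, class = "cohort_spec")
}

#' @export
print.cohort_spec <- function(x, ...) {
  cat(sprintf("Cohort spec (%s): %d men, %d women\n", x$preset, x$n_men,
              x$n_women))
  for (side in c("men", "women")) {
    m <- x[[side]]
    cat(sprintf("  %-5s weight %.1f +/- %.1f kg, height %.1f +/- %.1f cm, age %.1f +/- %.1f y\n",
                side, m$weight[1], m$weight[2], m$height[1], m$height[2],
                m$age[1], m$age[2]))
  }
  cat(sprintf("  BMR = %.1f W + %.0f G + %.0f + N(0, %.0f) kJ/d%s\n",
              x$true_coeffs["weight"], x$true_coeffs["gender"],
              x$true_coeffs["intercept"], x$residual_sd,
              if (x$truncate) " (range-truncated covariates)" else ""))
  invisible(x)
}

# One sex's covariates: bivariate normal weight/height (correlation rho),
# independent age. Age is always rejection-sampled against the observed age
# range (it does not enter the BMR mean structure, and subjects must be
# adults); weight and height are truncated only when requested.
sample_sex <- function(n, moments, rho, truncate, ranges) {
  draw <- function(m) {
    z1 <- stats::rnorm(m); z2 <- stats::rnorm(m); z3 <- stats::rnorm(m)
    data.frame(
      weight = moments$weight[1] + moments$weight[2] * z1,
      height = moments$height[1] +
        moments$height[2] * (rho * z1 + sqrt(1 - rho^2) * z2),
      age = moments$age[1] + moments$age[2] * z3
    )
  }
  in_range <- function(d) {
    # weight/height must stay physiological even in the untruncated model
    ok <- d$age >= ranges$age[1] & d$age <= ranges$age[2] &
      d$weight > 0 & d$height > 0
    if (truncate) {
      ok <- ok &
        d$weight >= ranges$weight[1] & d$weight <= ranges$weight[2] &
        d$height >= ranges$height[1] & d$height <= ranges$height[2]
    }
    ok
  }
  out <- draw(n)
  out <- out[in_range(out), , drop = FALSE]
  tries <- 0L
  while (nrow(out) < n) {
    extra <- draw(max(n, 100L))
    out <- rbind(out, extra[in_range(extra), , drop = FALSE])
    tries <- tries + 1L
    if (tries > 1000L) stop("rejection sampling failed: acceptance region too small")
  }
  out[seq_len(n), , drop = FALSE]
}

#' Generate a synthetic cohort
#'
#' Draws a subject table from a [cohort_spec()]: per-sex Normal covariates
#' and measured BMR equal to the spec's linear mean structure plus a Normal
#' residual. Fully reproducible for a given seed.
#'
#' @param spec A [cohort_spec()].
#' @param seed Integer seed; `NULL` leaves the RNG state alone.
#' @return Subject data frame with columns `id`, `sex`, `age`, `weight`,
#'   `height`, `bmr_measured` (men first).
#' @examples
#' cohort <- generate_cohort(cohort_spec(), seed = 1)
#' nrow(cohort)  # 232
#' @export
generate_cohort <- function(spec = cohort_spec(), seed = NULL) {
  stopifnot(inherits(spec, "cohort_spec"))
  if (!is.null(seed)) set.seed(seed)
  parts <- list()
  if (spec$n_men > 0L) {
    parts$men <- cbind(sex = "male",
                       sample_sex(spec$n_men, spec$men, spec$wh_corr,
                                  spec$truncate, spec$ranges))
  }
  if (spec$n_women > 0L) {
    parts$women <- cbind(sex = "female",
                         sample_sex(spec$n_women, spec$women, spec$wh_corr,
                                    spec$truncate, spec$ranges))
  }
  cohort <- do.call(rbind, parts)
  n <- nrow(cohort)
  g <- as.numeric(cohort$sex == "male")
  cohort$bmr_measured <- spec$true_coeffs[["intercept"]] +
    spec$true_coeffs[["weight"]] * cohort$weight +
    spec$true_coeffs[["gender"]] * g +
    stats::rnorm(n, 0, spec$residual_sd)
  data.frame(id = sprintf("S%03d", seq_len(n)),
             cohort[c("sex", "age", "weight", "height", "bmr_measured")],
             row.names = NULL)
}

#' Generate the cross-validation cohort
#'
#' Convenience wrapper for [generate_cohort()] with the
#' `"cross_validation"` preset (26 men, 44 women).
#'
#' @param seed Integer seed.
#' @param ... Overrides passed to [cohort_spec()].
#' @return Subject data frame.
#' @export
generate_validation_cohort <- function(seed = NULL, ...) {
  generate_cohort(cohort_spec(preset = "cross_validation", ...), seed = seed)
}

#' Gas-trace generator specification
#'
#' Parameters of a synthetic ventilated-hood recording whose steady-state
#' segment encodes a known true BMR: the Weir formula is inverted at the
#' given respiratory quotient to constant VO2/VCO2 targets, an
#' exponentially decaying habituation transient of relative amplitude
#' `transient_amp` (time constant `transient_minutes * 60 / 3` s, so the
#' transient has decayed to about 5 percent of its amplitude by the end of
#' `transient_minutes`) is prepended, and multiplicative Normal noise of
#' coefficient of variation `noise_cv` is applied per sample and gas.
#'
#' @param bmr_true True steady-state BMR, kJ/d.
#' @param rq Respiratory quotient VCO2/VO2, in [0.7, 1.0].
#' @param noise_cv Multiplicative noise CV (fraction, >= 0).
#' @param transient_minutes Habituation transient duration, minutes.
#' @param transient_amp Initial relative amplitude of the transient.
#' @param duration Session length, seconds.
#' @param interval Sampling interval, seconds.
#' @return An object of class `gas_trace_spec`.
#' @export
gas_trace_spec <- function(bmr_true, rq = 0.85, noise_cv = 0.03,
                           transient_minutes = 4, transient_amp = 0.15,
                           duration = 1800, interval = 5) {
  stopifnot(is.finite(bmr_true), bmr_true > 0,
            rq >= 0.7, rq <= 1.0, noise_cv >= 0,
            transient_minutes >= 0, duration > 0, interval > 0)
  structure(list(bmr_true = bmr_true, rq = rq, noise_cv = noise_cv,
                 transient_minutes = transient_minutes,
                 transient_amp = transient_amp,
                 duration = duration, interval = interval),
            class = "gas_trace_spec")
}

#' Generate a synthetic gas-exchange series
#'
#' @param spec A [gas_trace_spec()].
#' @param seed Integer seed; `NULL` leaves the RNG state alone.
#' @return A [gas_series()] sampled at `spec$interval` over `spec$duration`
#'   (first sample at t = 0), whose post-transient segment encodes
#'   `spec$bmr_true` through the Weir formula.
#' @examples
#' sp <- gas_trace_spec(bmr_true = 7268.8, rq = 0.8, noise_cv = 0,
#'                      transient_amp = 0)
#' head(generate_gas_series(sp))  # constant (0.25, 0.20) L/min
#' @export
generate_gas_series <- function(spec, seed = NULL) {
  stopifnot(inherits(spec, "gas_trace_spec"))
  if (!is.null(seed)) set.seed(seed)
  # invert the Weir formula at the given RQ: bmr = (c1 + c2 rq) vo2 * 1440 * 4.184
  vo2_ss <- spec$bmr_true / ((WEIR_O2 + WEIR_CO2 * spec$rq) *
                               MIN_PER_DAY * KJ_PER_KCAL)
  vco2_ss <- spec$rq * vo2_ss
  t <- seq(0, spec$duration - spec$interval, by = spec$interval)
  shape <- if (spec$transient_minutes > 0) {
    1 + spec$transient_amp * exp(-t / (spec$transient_minutes * 60 / 3))
  } else rep(1, length(t))
  noise <- function() {
    if (spec$noise_cv > 0) stats::rnorm(length(t), 1, spec$noise_cv) else 1
  }
  vo2 <- pmax(vo2_ss * shape * noise(), 0)
  vco2 <- pmax(vco2_ss * shape * noise(), 0)
  gas_series(t, vo2, vco2, interval = spec$interval)
}
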