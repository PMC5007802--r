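#' Construct a BMR prediction equation
#'
#' A prediction equation is a named set of sex-stratified, age-banded linear
#' formulas returning basal metabolic rate (BMR) in kJ/d from weight (kg),
#' height (cm) and age (years). Within a band the prediction is
#' `intercept + w * weight + h * height + a * age`.
#'
#' @param name Equation name (e.g. `"Singapore"`).
#' @param bands A data frame with columns `sex` (`"male"`/`"female"`),
#'   `age_min`, `age_max` (years), `intercept` (kJ/d), `w` (kJ/d per kg),
#'   `h` (kJ/d per cm) and `a` (kJ/d per year). For each sex the age bands
#'   must be non-overlapping and jointly cover the declared adult range.
#'   Dispatch is half-open `[age_min, age_max)` except for the oldest band
#'   of each sex, which includes its upper bound.
#' @return An object of class `bmr_equation`.
#' @seealso [builtin_equations()], [predict_bmr()]
#' @export
prediction_equation <- function(name, bands) {
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  bands <- as.data.frame(bands)
  needed <- c("sex", "age_min", "age_max", "intercept", "w", "h", "a")
  missing_cols <- setdiff(needed, names(bands))
  if (length(missing_cols)) {
    stop("equation bands lack column(s): ", paste(missing_cols, collapse = ", "))
  }
  bands <- bands[needed]
  bands$sex <- normalize_sex(bands$sex)
  for (col in needed[-1]) bands[[col]] <- as.numeric(bands[[col]])
  if (any(bands$age_min >= bands$age_max)) {
    stop("equation '", name, "': each band needs age_min < age_max")
  }
  for (sx in unique(bands$sex)) {
    b <- bands[bands$sex == sx, , drop = FALSE]
    b <- b[order(b$age_min), , drop = FALSE]
    if (nrow(b) > 1L && any(b$age_min[-1L] != b$age_max[-nrow(b)])) {
      stop("equation '", name, "' (", sx,
           "): age bands must be contiguous and non-overlapping")
    }
  }
  structure(list(name = name, bands = bands), class = "bmr_equation")
}

#' @export
print.bmr_equation <- function(x, ...) {
  cat("BMR prediction equation:", x$name, "\n")
  b <- x$bands
  for (i in seq_len(nrow(b))) {
    terms <- character(0)
    if (b$w[i] != 0) terms <- c(terms, paste0(format(b$w[i]), " W"))
    if (b$h[i] != 0) terms <- c(terms, paste0(format(b$h[i]), " H"))
    if (b$a[i] != 0) terms <- c(terms, paste0(format(b$a[i]), " A"))
    terms <- c(terms, format(b$intercept[i]))
    cat(sprintf("  %-6s %3g-%3g y: %s kJ/d\n", b$sex[i], b$age_min[i],
                b$age_max[i], paste(terms, collapse = " + ")))
  }
  invisible(x)
}

# Upper age bound used for single-band "Adult" equations.
ADULT_AGE_MAX <- 120

adult_bands <- function(m_int, m_w, m_h = 0, m_a = 0,
                        f_int, f_w, f_h = 0, f_a = 0) {
  data.frame(
    sex = c("male", "female"),
    age_min = 18, age_max = ADULT_AGE_MAX,
    intercept = c(m_int, f_int),
    w = c(m_w, f_w), h = c(m_h, f_h), a = c(m_a, f_a)
  )
}

#' Registry of seven anthropometric BMR prediction equations
#'
#' Returns the seven equations compared in the source study: the Singapore
#' equation (weight + gender), Harris-Benedict (HB), Henry (three age bands
#' per sex), Liu, Yang, Mifflin and Owen. All coefficients are in kJ/d at
#' their published precision; gender enters through per-sex intercepts.
#'
#' @return A named list of [prediction_equation()] objects, in accuracy-rank
#'   order of the source comparison: Singapore, HB, Henry, Liu, Yang,
#'   Mifflin, Owen.
#' @examples
#' eqs <- builtin_equations()
#' names(eqs)
#' eqs$Singapore
#' @export
builtin_equations <- function() {
  list(
    Singapore = prediction_equation("Singapore", adult_bands(
      m_int = 2788, m_w = 52.6, f_int = 1960, f_w = 52.6)),
    HB = prediction_equation("HB", adult_bands(
      m_int = 278, m_w = 57.5, m_h = 20.9, m_a = -28.2,
      f_int = 2783, f_w = 40.0, f_h = 7.7, f_a = -19.5)),
    Henry = prediction_equation("Henry", data.frame(
      sex = rep(c("male", "female"), each = 3),
      age_min = rep(c(18, 30, 60), 2),
      age_max = rep(c(30, 60, 70), 2),
      intercept = c(473, -574, -1070, -1180, -49, 45),
      w = c(60.0, 47.6, 47.8, 43.3, 34.2, 35.6),
      h = c(13.1, 22.6, 22.6, 25.7, 21.0, 17.6),
      a = 0)),
    Liu = prediction_equation("Liu", adult_bands(
      m_int = 227, m_w = 58.1, m_h = 17.4, m_a = -14.4,
      f_int = -243, f_w = 58.1, f_h = 17.4, f_a = -14.4)),
    Yang = prediction_equation("Yang", adult_bands(
      m_int = 877, m_w = 89, f_int = 277, f_w = 89)),
    Mifflin = prediction_equation("Mifflin", adult_bands(
      m_int = 21, m_w = 41.8, m_h = 26.2, m_a = -20.6,
      f_int = -674, f_w = 41.8, f_h = 26.2, f_a = -20.6)),
    Owen = prediction_equation("Owen", adult_bands(
      m_int = 3678, m_w = 42.7, f_int = 3326, f_w = 30.0))
  )
}

# Map user-facing sex labels onto the internal male/female coding.
normalize_sex <- function(sex) {
  s <- tolower(as.character(sex))
  out <- ifelse(s %in% c("m", "male", "man", "men"), "male",
         ifelse(s %in% c("f", "female", "woman", "women"), "female", NA))
  if (anyNA(out)) {
    bad <- unique(sex[is.na(out)])
    stop("unrecognised sex value(s): ", paste(bad, collapse = ", "),
         " (expected M/F or male/female)")
  }
  out
}

# Gender indicator used throughout: men = 1, women = 0.
sex_indicator <- function(sex) as.numeric(normalize_sex(sex) == "male")

#' Validate a subject table
#'
#' Subjects are held in a plain data frame with columns `id`, `sex`
#' (`"male"`/`"female"`), `age` (years), `weight` (kg), `height` (cm) and
#' optionally `bmr_measured` (kJ/d, `NA` allowed).
#'
#' @param subjects Data frame of subjects.
#' @param require_bmr If `TRUE`, every subject must carry a measured BMR.
#' @param min_age Lower age bound enforced on entry (years).
#' @return The validated data frame, with sex normalised and a
#'   `bmr_measured` column guaranteed to exist.
#' @export
validate_subjects <- function(subjects, require_bmr = FALSE, min_age = 18) {
  subjects <- as.data.frame(subjects)
  needed <- c("id", "sex", "age", "weight", "height")
  missing_cols <- setdiff(needed, names(subjects))
  if (length(missing_cols)) {
    stop("subject table lacks column(s): ", paste(missing_cols, collapse = ", "))
  }
  if (!"bmr_measured" %in% names(subjects)) subjects$bmr_measured <- NA_real_
  subjects$sex <- normalize_sex(subjects$sex)
  for (col in c("age", "weight", "height", "bmr_measured")) {
    subjects[[col]] <- as.numeric(subjects[[col]])
  }
  bad_row <- function(ok, what) {
    if (any(!ok)) {
      stop("invalid subject row(s) ", paste(which(!ok), collapse = ", "),
           ": ", what)
    }
  }
  bad_row(is.finite(subjects$weight) & subjects$weight > 0, "weight must be > 0")
  bad_row(is.finite(subjects$height) & subjects$height > 0, "height must be > 0")
  bad_row(is.finite(subjects$age) & subjects$age >= min_age,
          paste0("age must be >= ", min_age))
  if (require_bmr) {
    bad_row(is.finite(subjects$bmr_measured) & subjects$bmr_measured > 0,
            "measured BMR must be present and > 0")
  }
  subjects
}

# Index of the band (row of eq$bands) matching each subject, NA if none.
# The oldest band per sex includes its upper bound; others are [min, max).
match_band <- function(eq, sex, age) {
  b <- eq$bands
  top <- stats::ave(b$age_max, b$sex, FUN = max)
  vapply(seq_along(sex), function(i) {
    hit <- which(b$sex == sex[i] & age[i] >= b$age_min &
                   (age[i] < b$age_max | (b$age_max == top & age[i] == b$age_max)))
    if (length(hit)) hit[1L] else NA_integer_
  }, integer(1))
}

#' Evaluate a prediction equation on subjects
#'
#' Dispatches each subject to the (sex, age band) row of the equation and
#' returns `intercept + w*weight + h*height + a*age` in kJ/d.
#'
#' @param eq A [prediction_equation()].
#' @param subjects Subject data frame (see [validate_subjects()]).
#' @param extrapolate If `TRUE`, subjects whose age falls outside every band
#'   for their sex are evaluated with the nearest band's coefficients instead
#'   of raising an error.
#' @return Numeric vector of predicted BMR, kJ/d.
#' @examples
#' eqs <- builtin_equations()
#' s <- data.frame(id = "x", sex = "M", age = 30, weight = 79.2, height = 171.7)
#' predict_bmr(eqs$Singapore, s)  # 52.6 * 79.2 + 2788
#' @export
predict_bmr <- function(eq, subjects, extrapolate = FALSE) {
  stopifnot(inherits(eq, "bmr_equation"))
  subjects <- validate_subjects(subjects)
  idx <- match_band(eq, subjects$sex, subjects$age)
  if (anyNA(idx)) {
    if (extrapolate) {
      for (i in which(is.na(idx))) {
        b <- which(eq$bands$sex == subjects$sex[i])
        d <- pmax(eq$bands$age_min[b] - subjects$age[i],
                  subjects$age[i] - eq$bands$age_max[b], 0)
        idx[i] <- b[which.min(d)]
      }
    } else {
      i <- which(is.na(idx))[1L]
      stop("equation '", eq$name, "' has no age band for ",
           subjects$sex[i], " aged ", subjects$age[i],
           " (set extrapolate = TRUE to use the nearest band)")
    }
  }
  b <- eq$bands[idx, , drop = FALSE]
  b$intercept + b$w * subjects$weight + b$h * subjects$height + b$a * subjects$age
}

# TRUE where the equation has a band for (sex, age); used by skip policies.
has_band <- function(eq, sex, age) !is.na(match_band(eq, sex, age))

#' Body mass index
#'
#' @param weight Weight in kg (> 0).
#' @param height Height in cm (> 0).
#' @return BMI in kg/m^2: `weight / (height / 100)^2`.
#' @examples
#' compute_bmi(79.2, 171.7)
#' @export
compute_bmi <- function(weight, height) {
  if (any(!is.finite(weight) | weight <= 0)) stop("weight must be > 0")
  if (any(!is.finite(height) | height <= 0)) stop("height must be > 0")
  weight / (height / 100)^2
}

#' Classify BMI with Asian cut-offs
#'
#' Overweight is defined as BMI > 23.0 kg/m^2 and obesity as BMI > 27.5,
#' the cut-offs recommended for Asian populations (lower than the
#' conventional 25/30). Both boundaries are inclusive on the lower side:
#' a BMI of exactly 23.0 is not overweight and 27.5 is overweight.
#'
#' @param bmi BMI in kg/m^2 (> 0).
#' @param overweight Overweight cut-off, kg/m^2.
#' @param obese Obesity cut-off, kg/m^2.
#' @return Factor with levels `not_overweight`, `overweight`, `obese`.
#' @seealso [bmi_stratum()] for the two-way split used in accuracy tables.
#' @export
classify_bmi <- function(bmi, overweight = 23.0, obese = 27.5) {
  if (any(!is.finite(bmi) | bmi <= 0)) stop("bmi must be > 0")
  cut(bmi, breaks = c(0, overweight, obese, Inf),
      labels = c("not_overweight", "overweight", "obese"), right = TRUE)
}

#' Two-way BMI stratum
#'
#' The accuracy tables stratify subjects at a single BMI cut (default 23
#' kg/m^2), with the boundary counted in the lower stratum.
#'
#' @param bmi BMI in kg/m^2.
#' @param cut Cut point, kg/m^2.
#' @return Factor with levels `"<=cut"` and `">cut"`.
#' @export
bmi_stratum <- function(bmi, cut = 23.0) {
  if (any(!is.finite(bmi) | bmi <= 0)) stop("bmi must be > 0")
  factor(ifelse(bmi <= cut, paste0("<=", cut), paste0(">", cut)),
         levels = c(paste0("<=", cut), paste0(">", cut)))
}
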