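#' Read a subject cohort CSV
#'
#' Expected header: `id,sex,age,weight_kg,height_cm,bmr_kj_d` (the BMR
#' column is optional and may be blank). Sex is coded `M`/`F`; comma
#' separator, dot decimal, UTF-8.
#'
#' @param path File path.
#' @param require_bmr Require a measured BMR on every row.
#' @return Subject data frame (see [validate_subjects()]).
#' @export
read_cohort_csv <- function(path, require_bmr = FALSE) {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         fileEncoding = "UTF-8")
  needed <- c("id", "sex", "age", "weight_kg", "height_cm")
  missing_cols <- setdiff(needed, names(raw))
  if (length(missing_cols)) {
    stop(path, ": missing column(s): ", paste(missing_cols, collapse = ", "))
  }
  num <- function(col) {
    v <- raw[[col]]
    if (is.character(v)) v[!nzchar(trimws(v))] <- NA
    out <- suppressWarnings(as.numeric(v))
    bad <- which(!is.na(v) & is.na(out))
    if (length(bad)) {
      stop(path, " row ", bad[1L], ": non-numeric ", col, " value '",
           v[bad[1L]], "'")
    }
    out
  }
  subjects <- data.frame(
    id = as.character(raw$id),
    sex = raw$sex,
    age = num("age"),
    weight = num("weight_kg"),
    height = num("height_cm"),
    bmr_measured = if ("bmr_kj_d" %in% names(raw)) num("bmr_kj_d") else NA_real_
  )
  bad_sex <- which(!raw$sex %in% c("M", "F"))
  if (length(bad_sex)) {
    stop(path, " row ", bad_sex[1L], ": sex must be M or F, got '",
         raw$sex[bad_sex[1L]], "'")
  }
  tryCatch(validate_subjects(subjects, require_bmr = require_bmr),
           error = function(e) stop(path, ": ", conditionMessage(e),
                                    call. = FALSE))
}

#' Write a subject cohort CSV
#'
#' Inverse of [read_cohort_csv()]; numeric fields are written at full
#' precision (15 significant digits) so a write/read round trip preserves
#' them to well under 1e-9 relative.
#'
#' @param cohort Subject data frame.
#' @param path File path.
#' @return `path`, invisibly.
#' @export
write_cohort_csv <- function(cohort, path) {
  cohort <- validate_subjects(cohort)
  fmt <- function(x) ifelse(is.na(x), "", format(x, digits = 15,
                                                 scientific = FALSE,
                                                 trim = TRUE))
  out <- data.frame(
    id = cohort$id,
    sex = ifelse(cohort$sex == "male", "M", "F"),
    age = fmt(cohort$age),
    weight_kg = fmt(cohort$weight),
    height_cm = fmt(cohort$height),
    bmr_kj_d = fmt(cohort$bmr_measured)
  )
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE,
                   fileEncoding = "UTF-8")
  invisible(path)
}

#' Read a gas-exchange CSV
#'
#' Expected header: `t_s,vo2_l_min,vco2_l_min` at a uniform (5-s) cadence.
#'
#' @param path File path.
#' @param tolerance Relative tolerance on cadence uniformity.
#' @return A [gas_series()].
#' @export
read_gas_csv <- function(path, tolerance = 1e-6) {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  needed <- c("t_s", "vo2_l_min", "vco2_l_min")
  missing_cols <- setdiff(needed, names(raw))
  if (length(missing_cols)) {
    stop(path, ": missing column(s): ", paste(missing_cols, collapse = ", "))
  }
  gas_series(raw$t_s, raw$vo2_l_min, raw$vco2_l_min, tolerance = tolerance)
}

#' Write a gas-exchange CSV
#'
#' @param series A [gas_series()].
#' @param path File path.
#' @return `path`, invisibly.
#' @export
write_gas_csv <- function(series, path) {
  stopifnot(inherits(series, "gas_series"))
  out <- data.frame(t_s = series$t,
                    vo2_l_min = format(series$vo2, digits = 15, trim = TRUE),
                    vco2_l_min = format(series$vco2, digits = 15, trim = TRUE))
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

# Flat band table used by every registry serialisation format.
registry_to_table <- function(eqs) {
  if (inherits(eqs, "bmr_equation")) eqs <- list(eqs)
  do.call(rbind, lapply(eqs, function(e) {
    cbind(name = e$name, e$bands)
  }))
}

table_to_registry <- function(tab) {
  tab$sex <- normalize_sex(tab$sex)
  out <- lapply(split(tab, factor(tab$name, levels = unique(tab$name))),
                function(b) prediction_equation(b$name[1L],
                                                b[setdiff(names(b), "name")]))
  out[unique(tab$name)]
}

#' Write an equation registry
#'
#' Serialises one or more prediction equations as a flat band table
#' (fields `name, sex, age_min, age_max, intercept, w, h, a`). The format
#' follows the file extension: `.csv`, `.json`, or `.yaml`/`.yml`. All
#' formats preserve coefficients at full precision.
#'
#' @param eqs A [prediction_equation()] or list of them.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_equations <- function(eqs, path) {
  tab <- registry_to_table(eqs)
  rownames(tab) <- NULL
  ext <- tolower(tools::file_ext(path))
  if (ext == "csv") {
    out <- tab
    for (col in c("age_min", "age_max", "intercept", "w", "h", "a")) {
      out[[col]] <- format(out[[col]], digits = 15, trim = TRUE,
                           scientific = FALSE)
    }
    utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  } else if (ext == "json") {
    jsonlite::write_json(tab, path, digits = NA, auto_unbox = TRUE)
  } else if (ext %in% c("yaml", "yml")) {
    recs <- lapply(seq_len(nrow(tab)), function(i) as.list(tab[i, ]))
    yaml::write_yaml(list(equations = recs), path, precision = 15)
  } else {
    stop("unsupported registry format: .", ext)
  }
  invisible(path)
}

#' Read an equation registry
#'
#' @param path Path to a `.csv`, `.json` or `.yaml`/`.yml` registry written
#'   by [write_equations()] (or hand-authored in the same shape).
#' @return Named list of [prediction_equation()]s.
#' @export
read_equations <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  tab <- if (ext == "csv") {
    utils::read.csv(path, stringsAsFactors = FALSE)
  } else if (ext == "json") {
    jsonlite::fromJSON(path)
  } else if (ext %in% c("yaml", "yml")) {
    recs <- yaml::read_yaml(path)$equations
    do.call(rbind, lapply(recs, function(r) as.data.frame(r)))
  } else {
    stop("unsupported registry format: .", ext)
  }
  table_to_registry(as.data.frame(tab))
}

#' Write an evaluation report
#'
#' Writes the ranked summary table of [evaluate_equations()]. CSV output is
#' rounded the way the agreement tables are conventionally printed (kJ/d
#' and percentages to whole numbers, R^2 to 2 decimals, p-values to 4
#' significant digits); JSON output carries full precision.
#'
#' @param evaluation A `bmr_evaluation` (or its `table` data frame).
#' @param path Output path.
#' @param format `"csv"` or `"json"`; default follows the file extension.
#' @return `path`, invisibly.
#' @export
write_report <- function(evaluation, path, format = NULL) {
  tab <- if (inherits(evaluation, "bmr_evaluation")) evaluation$table
         else as.data.frame(evaluation)
  if (is.null(tab) || nrow(tab) == 0L) stop("empty report")
  if (is.null(format)) {
    format <- if (tolower(tools::file_ext(path)) == "json") "json" else "csv"
  }
  format <- match.arg(format, c("csv", "json"))
  if (format == "json") {
    jsonlite::write_json(tab, path, digits = NA, auto_unbox = TRUE,
                         na = "null")
  } else {
    out <- tab
    kj <- c("mean_pred", "sd_pred", "bias", "sd_diff", "loa_low", "loa_high")
    pct <- grep("^pct_", names(out), value = TRUE)
    for (col in c(kj, pct)) out[[col]] <- round(out[[col]])
    out$r2 <- round(out$r2, 2)
    for (col in c("p_paired_t", "ba_slope_p")) {
      out[[col]] <- signif(out[[col]], 4)
    }
    out$ba_slope <- signif(out$ba_slope, 4)
    utils::write.csv(out, path, row.names = FALSE)
  }
  invisible(path)
}

#' Read an evaluation report written as JSON
#'
#' @param path Path to a JSON report from [write_report()].
#' @return The report data frame.
#' @export
read_report_json <- function(path) {
  as.data.frame(jsonlite::fromJSON(path))
}
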