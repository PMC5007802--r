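test_that("built-in registry carries the seven published equations", {
  eqs <- builtin_equations()
  expect_length(eqs, 7L)
  expect_named(eqs, c("Singapore", "HB", "Henry", "Liu", "Yang", "Mifflin",
                      "Owen"))

  sg <- eqs$Singapore$bands
  expect_equal(sg$intercept[sg$sex == "male"], 2788)
  expect_equal(sg$intercept[sg$sex == "female"], 1960)
  expect_equal(sg$w, c(52.6, 52.6))

  yang <- eqs$Yang$bands
  expect_equal(yang$w, c(89, 89))
  expect_equal(yang$intercept[yang$sex == "male"], 877)
  expect_equal(yang$intercept[yang$sex == "female"], 277)

  # Henry is the only age-banded equation: three bands per sex, contiguous
  # over 18-70; all the others have a single adult band per sex
  henry <- eqs$Henry$bands
  expect_equal(nrow(henry), 6L)
  for (sx in c("male", "female")) {
    b <- henry[henry$sex == sx, ]
    expect_equal(b$age_min, c(18, 30, 60))
    expect_equal(b$age_max, c(30, 60, 70))
  }
  for (nm in setdiff(names(eqs), "Henry")) {
    expect_equal(nrow(eqs[[nm]]$bands), 2L, info = nm)
  }
})

test_that("predict_bmr reproduces hand-computed values", {
  eqs <- builtin_equations()
  s <- function(sex, age, weight, height = 165) {
    data.frame(id = "s", sex = sex, age = age, weight = weight,
               height = height)
  }
  expect_equal(predict_bmr(eqs$Singapore, s("M", 30, 79.2)),
               52.6 * 79.2 + 2788)
  expect_equal(predict_bmr(eqs$Owen, s("F", 40, 50)), 30.0 * 50 + 3326)
  expect_equal(predict_bmr(eqs$Henry, s("F", 45, 60, 160)),
               34.2 * 60 + 21.0 * 160 - 49)
  expect_equal(predict_bmr(eqs$HB, s("M", 30, 70, 170)),
               278 + 57.5 * 70 + 20.9 * 170 - 28.2 * 30)
  expect_equal(predict_bmr(eqs$Liu, s("F", 35, 55, 158)),
               58.1 * 55 + 17.4 * 158 - 14.4 * 35 - 243)

  # weight-only equations reduce to the intercept as weight -> 0
  w <- 63.7
  expect_equal(predict_bmr(eqs$Yang, s("M", 30, w)) - 89 * w, 877)
})

test_that("age-band dispatch is half-open with an inclusive top band", {
  henry <- builtin_equations()$Henry
  s <- function(age) data.frame(id = "s", sex = "M", age = age, weight = 70,
                                height = 170)
  at_band <- function(w, h, int) w * 70 + h * 170 + int
  # age exactly 30 falls in the middle band, not the first
  expect_equal(predict_bmr(henry, s(30)), at_band(47.6, 22.6, -574))
  expect_equal(predict_bmr(henry, s(29.999)), at_band(60.0, 13.1, 473))
  # the oldest band includes its upper bound
  expect_equal(predict_bmr(henry, s(70)), at_band(47.8, 22.6, -1070))
  expect_error(predict_bmr(henry, s(75)), "no age band")
  # nearest-band extrapolation reuses the 60-70 coefficients (age has no
  # slope in Henry, so the value equals the band formula)
  expect_equal(predict_bmr(henry, s(75), extrapolate = TRUE),
               at_band(47.8, 22.6, -1070))
})

test_that("predictions are linear: cohort mean equals prediction at the mean", {
  eqs <- builtin_equations()
  set.seed(61)
  for (rep in 1:5) {
    n <- 40
    subjects <- data.frame(
      id = seq_len(n), sex = "M", age = runif(n, 30, 59.9),
      weight = runif(n, 50, 110), height = runif(n, 150, 190)
    )
    at_mean <- data.frame(id = "m", sex = "M", age = mean(subjects$age),
                          weight = mean(subjects$weight),
                          height = mean(subjects$height))
    for (eq in eqs) {
      expect_equal(mean(predict_bmr(eq, subjects)),
                   predict_bmr(eq, at_mean), tolerance = 1e-12,
                   info = eq$name)
    }
  }
})

test_that("BMI is computed and classified with the Asian cut-offs", {
  expect_equal(round(compute_bmi(79.2, 171.7), 1), 26.9)
  expect_equal(compute_bmi(100, 200), 25.0)
  expect_equal(round(compute_bmi(66.1, 159.9), 1), 25.9)
  expect_error(compute_bmi(-5, 170), "weight")
  expect_error(compute_bmi(70, 0), "height")

  expect_equal(as.character(classify_bmi(c(23.0, 27.5, 30.1, 18))),
               c("not_overweight", "overweight", "obese", "not_overweight"))
  # the two-way split used by the accuracy tables keeps 23.0 in the lower
  # stratum
  expect_equal(as.character(bmi_stratum(c(23, 23.01))), c("<=23", ">23"))
})

test_that("registry serialisation round-trips with identical predictions", {
  eqs <- builtin_equations()
  subjects <- random_subjects(1000, seed = 99)
  for (ext in c("yaml", "csv", "json")) {
    path <- withr::local_tempfile(fileext = paste0(".", ext))
    write_equations(eqs, path)
    back <- read_equations(path)
    expect_named(back, names(eqs))
    for (nm in names(eqs)) {
      expect_identical(predict_bmr(back[[nm]], subjects, extrapolate = TRUE),
                       predict_bmr(eqs[[nm]], subjects, extrapolate = TRUE),
                       info = paste(ext, nm))
    }
  }
})

test_that("subject validation rejects impossible anthropometry", {
  base <- data.frame(id = "a", sex = "F", age = 30, weight = 60, height = 160)
  expect_silent(validate_subjects(base))
  expect_error(validate_subjects(transform(base, weight = -5)), "weight")
  expect_error(validate_subjects(transform(base, age = 15)), "age")
  expect_error(validate_subjects(transform(base, sex = "X")), "sex")
  expect_error(validate_subjects(base, require_bmr = TRUE), "BMR")
})
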