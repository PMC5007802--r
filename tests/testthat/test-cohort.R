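test_that("generated cohorts match the specified moments", {
  spec <- cohort_spec()
  cohort <- generate_cohort(spec, seed = 8)
  expect_equal(nrow(cohort), 232L)
  expect_equal(sum(cohort$sex == "male"), 121L)

  men <- cohort[cohort$sex == "male", ]
  women <- cohort[cohort$sex == "female", ]
  # sample means within 3 standard errors of the spec moments
  expect_lt(abs(mean(men$weight) - 79.2), 3 * 14.9 / sqrt(121))
  expect_lt(abs(mean(men$height) - 171.7), 3 * 5.9 / sqrt(121))
  expect_lt(abs(mean(women$weight) - 66.1), 3 * 16.1 / sqrt(111))
  expect_lt(abs(mean(women$height) - 159.9), 3 * 6.2 / sqrt(111))
  # ages always lie inside the observed study range
  expect_true(all(cohort$age >= 21.6 & cohort$age <= 66.8))
})

test_that("the grand mean BMR and predicted-value spread match the study summary", {
  # mean measured BMR across seeds ~ 6230 kJ/d
  means <- vapply(1:50, function(s) {
    mean(generate_cohort(cohort_spec(), seed = s)$bmr_measured)
  }, numeric(1))
  expect_lt(abs(mean(means) - 6230), 60)

  # SD of Singapore-equation predictions at population scale ~ 1115 kJ/d
  big <- cohort_spec(n_men = 60500, n_women = 55500)
  cohort <- generate_cohort(big, seed = 9)
  pred <- predict_bmr(builtin_equations()$Singapore, cohort)
  expect_equal(sd(pred), 1115, tolerance = 0.02)
})

test_that("cohort generation is deterministic given a seed", {
  a <- generate_cohort(cohort_spec(), seed = 12)
  b <- generate_cohort(cohort_spec(), seed = 12)
  expect_identical(a, b)

  f1 <- withr::local_tempfile(fileext = ".csv")
  f2 <- withr::local_tempfile(fileext = ".csv")
  write_cohort_csv(a, f1)
  write_cohort_csv(b, f2)
  expect_identical(readLines(f1), readLines(f2))
})

test_that("zero residual SD puts every subject on the plane (R^2 = 1)", {
  spec <- cohort_spec(residual_sd = 0)
  cohort <- generate_cohort(spec, seed = 3)
  fit <- fit_ols(cohort$bmr_measured,
                 data.frame(weight = cohort$weight,
                            gender = as.numeric(cohort$sex == "male")))
  expect_equal(fit$r2, 1, tolerance = 1e-12)
  expect_equal(unname(fit$coefficients), c(1960, 52.6, 828),
               tolerance = 1e-9)
})

test_that("the cross-validation preset reproduces its counts", {
  cohort <- generate_validation_cohort(seed = 2)
  expect_equal(nrow(cohort), 70L)
  expect_equal(sum(cohort$sex == "male"), 26L)

  # single-sex variant is allowed
  women_only <- generate_validation_cohort(seed = 2, n_men = 0)
  expect_equal(unique(women_only$sex), "female")
  expect_error(stepwise_derive(women_only), "single-sex")
})

test_that("optional truncation keeps covariates inside the observed ranges", {
  spec <- cohort_spec(truncate = TRUE)
  cohort <- generate_cohort(spec, seed = 21)
  expect_true(all(cohort$weight >= 39.3 & cohort$weight <= 113.1))
  expect_true(all(cohort$height >= 147.4 & cohort$height <= 189.3))

  expect_error(
    cohort_spec(truncate = TRUE,
                ranges = list(weight = c(500, 600), height = c(147, 190),
                              age = c(21, 67))),
    "infeasible")
})

test_that("optional weight-height correlation is honoured", {
  spec <- cohort_spec(n_men = 4000, n_women = 0, wh_corr = 0.4)
  men <- generate_cohort(spec, seed = 31)
  expect_equal(cor(men$weight, men$height), 0.4, tolerance = 0.06)
  spec0 <- cohort_spec(n_men = 4000, n_women = 0)
  men0 <- generate_cohort(spec0, seed = 31)
  expect_lt(abs(cor(men0$weight, men0$height)), 0.06)
})

test_that("noiseless gas traces invert the Weir formula exactly", {
  sp <- gas_trace_spec(bmr_true = (3.941 * 0.25 + 1.106 * 0.20) * 1440 * 4.184,
                       rq = 0.8, noise_cv = 0, transient_amp = 0)
  series <- generate_gas_series(sp)
  expect_equal(unique(round(series$vo2, 12)), 0.25)
  expect_equal(unique(round(series$vco2, 12)), 0.20)
  expect_equal(nrow(series), 360L)
  expect_equal(series$t[1], 0)
})

test_that("a long, large habituation transient pushes the window past it", {
  sp <- gas_trace_spec(bmr_true = 6000, transient_amp = 0.5,
                       transient_minutes = 10, noise_cv = 0.01)
  series <- generate_gas_series(sp, seed = 44)
  res <- series_to_bmr(series)
  expect_gte(res$window$start, 600)
})
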