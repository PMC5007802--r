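test_that("agreement statistics match hand arithmetic", {
  # differences {-1, 0, 1}: zero bias, unit SD, limits at +/-2
  st <- agreement_stats(c(10, 10, 10), c(9, 10, 11))
  expect_equal(st$bias, 0)
  expect_equal(st$sd_diff, 1)
  expect_equal(st$loa_low, -2)
  expect_equal(st$loa_high, 2)

  # identity: all statistics collapse
  st <- agreement_stats(c(5000, 6000, 7000), c(5000, 6000, 7000))
  expect_equal(st$bias, 0)
  expect_equal(st$sd_diff, 0)
  expect_equal(c(st$loa_low, st$loa_high), c(0, 0))
  expect_equal(st$r2, 1)
  expect_true(is.na(st$p_paired_t))

  expect_error(agreement_stats(1:4, 1:3), "equal length")
  expect_error(agreement_stats(1:2, 1:2), "at least 3")
})

test_that("mean predicted equals mean measured plus bias, exactly", {
  set.seed(17)
  measured <- rnorm(50, 6000, 1000)
  predicted <- measured + rnorm(50, 100, 400)
  st <- agreement_stats(measured, predicted)
  expect_identical(st$mean_pred, st$mean_meas + st$bias)
})

test_that("limits of agreement use bias +/- k * SD and cover ~95.45% of Normal differences", {
  # the arithmetic identity itself
  d <- c(56 - 407, 56, 56 + 407)  # mean 56, SD 407
  m <- c(5500, 6000, 6500)
  st <- agreement_stats(m, m + d)
  expect_equal(st$bias, 56)
  expect_equal(st$sd_diff, 407)
  expect_equal(st$loa_high, 870)
  expect_equal(st$loa_low, -758)

  # coverage of +/-2 SD limits for Normal differences
  set.seed(4242)
  n <- 10000
  measured <- rnorm(n, 6230, 1100)
  predicted <- measured + rnorm(n, 50, 500)
  st <- agreement_stats(measured, predicted)
  inside <- mean(predicted - measured >= st$loa_low &
                   predicted - measured <= st$loa_high)
  expect_gt(inside, 0.9545 - 0.02)
  expect_lt(inside, 0.9545 + 0.02)
})

test_that("difference-vs-average regression flags directional bias", {
  set.seed(31)
  measured <- rnorm(100, 6000, 800)
  # predictions compressed toward the mean produce a negative slope
  predicted <- 6000 + 0.6 * (measured - 6000) + rnorm(100, 0, 100)
  st <- agreement_stats(measured, predicted)
  expect_lt(st$ba_slope, -0.2)
  expect_lt(st$ba_slope_p, 0.001)

  # unbiased predictions do not
  predicted <- measured + rnorm(100, 0, 300)
  st <- agreement_stats(measured, predicted)
  expect_lt(abs(st$ba_slope), 0.4)
})

test_that("accuracy classification partitions at the +/-10% boundary", {
  expect_equal(as.character(accuracy_classify(6000, c(6600, 6601, 5400, 5399))),
               c("accurate", "over", "accurate", "under"))
  expect_error(accuracy_classify(-1, 5000), "> 0")

  # every pair lands in exactly one class; proportions sum to 1
  set.seed(53)
  measured <- runif(500, 4000, 9000)
  predicted <- measured * runif(500, 0.7, 1.3)
  cls <- accuracy_classify(measured, predicted)
  expect_false(anyNA(cls))
  expect_equal(sum(table(cls)), 500)
  expect_equal(sum(prop.table(table(cls))), 1)
})

test_that("accuracy breakdown stratifies by BMI and handles empty strata", {
  eq <- builtin_equations()$Singapore
  cohort <- generate_cohort(cohort_spec(), seed = 19)

  # perfect predictions: 0/100/0 everywhere
  perfect <- cohort
  perfect$bmr_measured <- predict_bmr(eq, perfect)
  acc <- accuracy_breakdown(perfect, eq)
  expect_equal(acc$pct_accurate, c(100, 100, 100))
  expect_equal(acc$pct_under, c(0, 0, 0))

  # strata percentages sum to 100 at full precision
  acc <- accuracy_breakdown(cohort, eq)
  expect_equal(acc$stratum, c("all", "<=23", ">23"))
  expect_equal(acc$pct_under + acc$pct_accurate + acc$pct_over,
               rep(100, 3), tolerance = 1e-9)
  expect_equal(acc$n[2] + acc$n[3], acc$n[1])

  # one lean subject predicted 20% high: all-over, obese stratum absent
  one <- data.frame(id = "x", sex = "F", age = 30, weight = 50, height = 170,
                    bmr_measured = 5000)
  stopifnot(compute_bmi(50, 170) <= 23)
  eq12 <- prediction_equation("x1.2", data.frame(
    sex = "female", age_min = 18, age_max = 120,
    intercept = 6000, w = 0, h = 0, a = 0))
  acc <- accuracy_breakdown(one, eq12)
  expect_equal(acc$pct_over[acc$stratum == "all"], 100)
  expect_equal(acc$pct_accurate[acc$stratum == "all"], 0)
  expect_true(is.na(acc$pct_over[acc$stratum == ">23"]))
})

test_that("evaluate_equations ranks by accuracy and is reproducible", {
  cohort <- generate_cohort(cohort_spec(), seed = 23)
  ev <- evaluate_equations(cohort)
  expect_equal(nrow(ev$table), 7L)
  expect_true(all(diff(ev$table$pct_accurate_all) <= 0))
  expect_equal(ev$table$equation[1], "Singapore")

  # bit-identical on re-run: no hidden state
  ev2 <- evaluate_equations(cohort)
  expect_identical(ev$table, ev2$table)

  # single-equation registry
  ev1 <- evaluate_equations(cohort, builtin_equations()["Owen"])
  expect_equal(nrow(ev1$table), 1L)

  # subjects outside Henry's bands are skipped and counted
  old <- data.frame(id = c("a", "b", "c"), sex = "M", age = 75,
                    weight = c(70, 75, 80), height = 170,
                    bmr_measured = c(6000, 6200, 6400))
  ev_old <- evaluate_equations(old, builtin_equations()[c("Henry", "Owen")])
  henry_row <- ev_old$table[ev_old$table$equation == "Henry", ]
  expect_equal(henry_row$n, 0L)
  expect_equal(henry_row$n_skipped, 3L)
  expect_true(is.na(henry_row$bias))
  expect_error(
    evaluate_equations(old, builtin_equations()["Henry"], policy = "fail"),
    "no age band")
})
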