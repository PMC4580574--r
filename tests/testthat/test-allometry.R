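test_that("log transform is exact and names offenders", {
  expect_equal(log_transform(c(1, 10, 100)), c(0, 1, 2))
  expect_equal(log_transform(10^0.5), 0.5)
  expect_equal(log_transform(29.26), oracle$log10_dsl_min, tolerance = 1e-14)
  expect_error(log_transform(c(A = 3, B = -1)), "specimen B")
})

test_that("SMA fit matches closed forms on exact lines", {
  x <- c(0, 1, 2, 3)
  f <- fit_sma(x, 2 * x + 1)
  expect_equal(f$slope, 2)
  expect_equal(f$intercept, 1)
  expect_equal(f$r2, 1)
  expect_equal(f$ci_low, f$ci_high)
  expect_true(f$exact)
  # sign comes from the correlation
  fneg <- fit_sma(x, -x)
  expect_equal(fneg$slope, -1)
})

test_that("SMA slope equals sign(r) sy/sx and the lm geometric mean", {
  set.seed(21)
  for (i in 1:5) {
    x <- rnorm(10)
    y <- 1.3 * x + rnorm(10, 0, 0.4)
    f <- fit_sma(x, y)
    expect_equal(f$slope, sign(cor(x, y)) * sd(y) / sd(x), tolerance = 1e-10)
    b_yx <- unname(coef(lm(y ~ x))[2])
    b_xy <- unname(coef(lm(x ~ y))[2])
    expect_equal(f$slope, sign(cor(x, y)) * sqrt(abs(b_yx / b_xy)),
                 tolerance = 1e-10)
    # axis-swap reciprocity
    expect_equal(f$slope * fit_sma(y, x)$slope, 1, tolerance = 1e-10)
  }
})

test_that("degenerate SMA inputs raise contract errors", {
  expect_error(fit_sma(c(1, 2), c(1, 2)), "n >= 3")
  expect_error(fit_sma(rep(1, 5), 1:5), "zero variance")
  expect_error(fit_sma(1:5, rep(2, 5)), "zero variance")
})

test_that("data exactly on the null slope give p = 1", {
  x <- log10(c(2, 5, 11, 23, 41))
  y <- 3 * x - 0.7
  out <- slope_test(x, y, 3)
  expect_equal(out$p_value, 1)
  expect_equal(out$test_statistic, 0)
})

test_that("slope test holds its nominal type-I error under H0", {
  set.seed(99)
  b0 <- 3; n <- 13; reps <- 2000
  rej <- 0L
  for (i in seq_len(reps)) {
    x <- rnorm(n, 0, 0.4)
    y <- b0 * (0.9 * x + sqrt(1 - 0.81) * rnorm(n, 0, 0.4))
    if (slope_test(x, y, b0)$p_value < 0.05) rej <- rej + 1L
  }
  expect_lt(abs(rej / reps - 0.05), 0.015)
})

test_that("SMA confidence intervals cover the true slope at nominal rate", {
  set.seed(100)
  n <- 13; true_slope <- 2; cover <- 0L; reps <- 500
  for (i in seq_len(reps)) {
    x <- rnorm(n, 0, 0.4)
    y <- true_slope * (0.9 * x + sqrt(1 - 0.81) * rnorm(n, 0, 0.4))
    f <- fit_sma(x, y)
    if (f$ci_low <= true_slope && true_slope <= f$ci_high) cover <- cover + 1L
  }
  expect_lt(abs(cover / reps - 0.95), 0.03)
})

test_that("negative allometry of middle-ear volume on skull size is detected", {
  # observed exponent 1.9735 with low noise at n = 13 must reject b0 = 3
  gen <- generate_growth_series(
    growth_series_config(seed = 8, n = 13, noise_sd_log10 = 0.02))
  rep <- run_allometry(gen$series)
  gms <- rep[rep$regression == "ME_v on GMS", ]
  expect_lt(gms$p, 0.05)
  expect_lt(gms$slope, 3)
  expect_equal(gms$decision, "negative allometry")
})

test_that("isometry of tympanum area with middle-ear volume is not rejected", {
  gen <- generate_growth_series(
    isometric_growth_config(seed = 9, n = 13, noise_sd_log10 = 0.02))
  rep <- run_allometry(gen$series)
  tsa <- rep[rep$regression == "ME_v on T_sa", ]
  expect_gt(tsa$p, 0.05)
  expect_equal(tsa$decision, "isometry not rejected")
})

test_that("run_allometry validates pairs and builds the report shape", {
  gen <- generate_growth_series(growth_series_config(seed = 10, n = 13))
  rep <- run_allometry(gen$series)
  expect_equal(names(rep),
               c("regression", "n", "r2", "slope", "ci_low", "ci_high",
                 "intercept", "null_slope", "t", "p", "decision"))
  expect_equal(nrow(rep), 3)
  expect_true(all(rep$ci_low <= rep$slope & rep$slope <= rep$ci_high))
  expect_true(all(rep$r2 >= 0 & rep$r2 <= 1))

  # constant predictor -> degenerate data
  bad <- gen$series
  bad$braincase_volume_mm3 <- 5
  expect_error(run_allometry(bad), "zero variance")

  # fewer than 3 complete cases
  short <- gen$series
  short$middle_ear_volume_mm3[3:13] <- NA
  expect_error(run_allometry(short), "fewer than 3")

  expect_equal(isometry_null("volume_on_linear"), 3)
  expect_equal(isometry_null("volume_on_area"), 1.5)
  expect_equal(isometry_null("volume_on_volume"), 1)
})
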