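test_that("mixed-model slope collapses to OLS for balanced zero-variance data", {
  ages <- 55:70
  df <- do.call(rbind, lapply(c("P01", "P02"), function(p) {
    data.frame(value = 3 + 0.5 * ages, age = ages, patient = p, eye = "right")
  }))
  df$value <- df$value + with_seed(8, rnorm(nrow(df), 0, 0.2))
  fit <- suppressWarnings(fit_lmm(df))
  ols <- unname(coef(lm(value ~ age, df))["age"])
  expect_lt(abs(fit$slope - ols), 1e-6)
  expect_true(fit$slope_ci[1] <= fit$slope && fit$slope <= fit$slope_ci[2])
})

test_that("mixed-model estimates recover a planted slope with both eyes", {
  hp <- hinge_params(50, 0, 0.53, 0, 0.5, 0.2, 0.3)
  df <- with_seed(11, sim_hinge_cohort(hp, 55:70, n_patients = 12))
  fit <- fit_lmm(df)
  expect_equal(fit$slope, 0.53, tolerance = 0.05)
  expect_gt(fit$chi2, 50)
  expect_lt(fit$p, 1e-6)
  expect_equal(sum(fit$vc >= 0), 3)
  expect_equal(fit$n_eyes, 24)

  # invariance to patient relabeling
  df2 <- df
  df2$patient <- factor(df2$patient,
                        labels = with_seed(13, sample(sprintf("Z%02d", 1:12))))
  fit2 <- fit_lmm(df2)
  expect_equal(fit2$slope, fit$slope, tolerance = 1e-8)

  # duplicating every row leaves the point estimate essentially unchanged
  fit3 <- fit_lmm(rbind(df, df))
  expect_equal(fit3$slope, fit$slope, tolerance = 1e-4)
})

test_that("mixed-model guards: inclusion rule and underdetermined data", {
  df <- data.frame(value = c(1, 2, 1.5), age = c(60, 61, 62),
                   patient = c("A", "A", "B"), eye = "right")
  # B has one visit; after inclusion only A remains with 2 ages
  expect_error(fit_lmm(df), "underdetermined")
})

test_that("likelihood-ratio test holds its size under the null", {
  # null: no age effect, only patient structure; ages permuted each rep
  n_rej <- 0
  reps <- 400
  with_seed(606, {
    for (i in seq_len(reps)) {
      df <- do.call(rbind, lapply(1:8, function(p) {
        data.frame(value = rnorm(1, 0, 1) + rnorm(5, 0, 0.5),
                   age = sample(60:64), patient = p, eye = "right")
      }))
      f <- suppressWarnings(fit_lmm(df))
      if (f$p < 0.05) n_rej <- n_rej + 1
    }
  })
  expect_gt(n_rej / reps, 0.005)
  expect_lt(n_rej / reps, 0.11)
})

test_that("hinge fit recovers a noiseless breakpoint to within the grid step", {
  hp <- hinge_params(70.3, 0, 0.05, 0.2)
  df <- data.frame(value = hinge_value(hp, 55:85), age = 55:85, patient = "P01")
  fit <- fit_hinge(df, n_boot = 0)
  expect_lt(abs(fit$psi - 70.3), 0.1)
  expect_equal(fit$pre_slope, 0, tolerance = 1e-6)
  expect_equal(fit$post_slope, 0.05, tolerance = 1e-4)
  expect_false(fit$indeterminate)
})

test_that("hinge fit flags collinear data and never beats it with structure", {
  df_line <- data.frame(value = 1 + 0.3 * (40:70), age = 40:70, patient = "P01")
  fit <- suppressWarnings(fit_hinge(df_line, n_boot = 0))
  expect_true(fit$indeterminate)
  expect_equal(fit$pre_slope, fit$post_slope, tolerance = 1e-6)

  # property: hinge RSS never exceeds the single-line RSS
  with_seed(77, {
    for (i in 1:12) {
      a <- sort(runif(40, 45, 80))
      y <- rnorm(40, 0.2 * a, 1)
      f <- suppressWarnings(fit_hinge(data.frame(value = y, age = a, patient = rep(1:8, 5)),
                                      n_boot = 0))
      expect_lte(f$rss, f$rss_line + 1e-8)
    }
  })
})

test_that("hinge bootstrap CI is seeded, ordered, and covers a noisy truth", {
  hp <- hinge_params(60, 0, 0.4, 1, 0.3, 0.1, 0.2)
  df <- with_seed(5, sim_hinge_cohort(hp, 52:68, n_patients = 10))
  f1 <- with_seed(9, fit_hinge(df, n_boot = 99))
  f2 <- with_seed(9, fit_hinge(df, n_boot = 99))
  expect_identical(f1$psi_ci, f2$psi_ci)
  expect_lt(f1$psi_ci[1], f1$psi_ci[2])
  expect_true(f1$psi_ci[1] <= 60 && 60 <= f1$psi_ci[2])
})

test_that("repeated-measures correlation matches the reference implementation", {
  # fixture values frozen from an independent external implementation
  fx <- data.frame(
    subject = rep(c("S0", "S1", "S2", "S3"), each = 5),
    x = c(0.1523585399, 0.4800079469, 2.3752255979, 3.4702823582, 3.0244824057,
          0.4396989874, 1.3888959677, 2.0330153488, 3.5636206035, 4.2337546711,
          -0.0924311818, 0.6595352278, 2.6112706693, 2.9227352590, 3.7858360889,
          1.0708238004, 0.7967924918, 1.7438786355, 2.5931136359, 4.3079897113),
    y = c(9.2103611771, 10.4734946397, 11.6788106637, 12.7644650763, 11.8224551752,
          12.7502544659, 14.3692423230, 13.9551944584, 16.4658116937, 16.3520555992,
          15.6795615692, 16.9002446121, 18.3448273805, 18.6271010353, 19.3302435732,
          20.6469396453, 19.5576707731, 19.8069933745, 20.4973540577, 22.9018067205))
  rc <- rm_correlation(fx$x, fx$y, fx$subject)
  expect_equal(rc$r, 0.949015086568, tolerance = 1e-9)
  expect_equal(rc$df, 15)
  expect_equal(rc$p, 6.3978692238e-09, tolerance = 1e-6)
  expect_equal(rc$ci, c(0.8611951144, 0.9818154179), tolerance = 1e-7)
})

test_that("repeated-measures correlation absorbs subject offsets", {
  x <- with_seed(3, rep(rnorm(6), times = 4) + rnorm(24, 0, 0.1))
  subject <- rep(1:4, each = 6)
  # exact copies: r = 1 (the F test degenerates on a perfect fit)
  expect_equal(suppressWarnings(rm_correlation(x, x, subject)$r), 1)
  # per-subject constant offsets on both series leave r at 1
  y <- x + rep(c(10, -4, 7, 0), each = 6)
  expect_equal(suppressWarnings(rm_correlation(x, y, subject)$r), 1)
  # general invariance to adding any per-subject constant
  z <- with_seed(4, x + rnorm(24, 0, 0.2))
  r0 <- rm_correlation(x, z, subject)$r
  r1 <- rm_correlation(x, z + rep(c(3, -2, 5, 11), each = 6), subject)$r
  expect_equal(r1, r0, tolerance = 1e-12)
})

test_that("repeated-measures correlation drops single-pair subjects with warning", {
  x <- c(1, 2, 3, 4, 9, 1.2, 2.1, 3.2, 4.1)
  y <- c(1, 2, 3, 4, 5, 1.1, 2.2, 3.1, 4.2)
  subject <- c("A", "A", "A", "A", "B", "C", "C", "C", "C")
  expect_warning(rc <- rm_correlation(x, y, subject), "single pair")
  expect_equal(rc$n_subjects, 2)
})

test_that("dynamic-range normalization reproduces the circle-rate arithmetic", {
  expect_equal(default_dynamic_range("sqrtAA_14mm"), sqrt(pi * 49))
  expect_equal(normalized_rate(0.53, default_dynamic_range("sqrtAA_14mm")),
               4.27, tolerance = 0.002)
  expect_equal(normalized_rate(0.24, default_dynamic_range("sqrtAA_6mm")),
               4.51, tolerance = 0.002)
  expect_equal(normalized_rate(0, 5), 0)
  expect_equal(normalized_rate(-257, default_dynamic_range("EZ_total")),
               4.28, tolerance = 0.002)
  expect_equal(normalized_rate(-4.7, default_dynamic_range("CRT", baseline_median = 226.5)),
               2.075, tolerance = 0.002)
  expect_error(normalized_rate(1, 0), "positive")
  expect_error(default_dynamic_range("CRT"), "baseline_median")
})

test_that("end-stage exclusion and Bonferroni behave per protocol", {
  rec <- data.frame(value = c(0.3, 1.4, 2.6), end_stage = c(FALSE, FALSE, TRUE))
  kept <- filter_endstage_bcva(rec)
  expect_equal(kept$value, c(0.3, 1.4))
  expect_identical(filter_endstage_bcva(rec[1:2, ]), rec[1:2, ])
  expect_warning(out <- filter_endstage_bcva(rec[3, , drop = FALSE]), "end-stage")
  expect_equal(nrow(out), 0)

  expect_equal(bonferroni_adjust(0.01, 4), 0.04)
  expect_equal(bonferroni_adjust(0.5, 4), 1)
  expect_equal(bonferroni_adjust(0.2, 1), 0.2)
  expect_error(bonferroni_adjust(1.2, 2), "\\[0, 1\\]")
})
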