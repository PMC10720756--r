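test_that("generated anatomy respects pixel geometry, laterality, and the seed", {
  cfg <- cohort_config(pixel_scale_range = c(11.5, 11.5),
                       fovea_disc_distance_range = c(4600, 4600),
                       image_size = c(1000, 1152), seed = 42)
  an <- generate_anatomy(cfg, 1, "right")
  # 4600 um at 11.5 um/px = 400 px, already 20-superpixel compatible
  expect_equal(fovea_disc_dx(an), 400)
  expect_identical(an$laterality, "right")
  expect_true(all(an$onh_xy >= 0) && an$onh_xy[1] <= cfg$image_size[2] - 1)

  # determinism: same seed and identity give identical anatomy
  expect_identical(generate_anatomy(cfg, 1, "right"), an)
  expect_false(identical(generate_anatomy(cfg, 2, "right"), an))

  # left eye: ONH temporal of fovea pre-flip, nasal after flipping
  al <- generate_anatomy(cfg, 1, "left")
  expect_lt(al$onh_xy[1], al$fovea_xy[1])
  ex <- faf_exam(matrix(0.5, 1000, 1152), matrix(FALSE, 1000, 1152), NULL,
                 al, "P01", "left", 60)
  flipped <- flip_to_right_eye(ex)
  expect_gt(flipped$anatomy$onh_xy[1], flipped$anatomy$fovea_xy[1])
})

test_that("anatomy generation rejects unrepresentable configurations", {
  bad <- cohort_config(pixel_scale_range = c(300, 300),
                       fovea_disc_distance_range = c(4600, 4600),
                       image_size = c(448, 576))
  expect_error(generate_anatomy(bad, 1, "right"), "not representable")
  narrow <- cohort_config(pixel_scale_range = c(11.5, 11.5),
                          fovea_disc_distance_range = c(4600, 4600),
                          image_size = c(448, 576))
  expect_error(generate_anatomy(narrow, 1, "right"), "image width")
})

test_that("hinge series reproduces the deterministic trajectory exactly", {
  hp <- hinge_params(53.9, 0, 0.53, intercept_at_breakpoint = 2)
  # ten years past the breakpoint at 0.53/y adds 5.3
  expect_equal(hinge_value(hp, 63.9), 2 + 5.3)
  expect_equal(hinge_value(hp, 53.9), 2)  # hinge vertex
  expect_equal(hinge_value(hp, 43.9), 2)  # flat pre-segment
  s <- with_seed(1, simulate_hinge_series(hp, c(43.9, 53.9, 63.9)))
  expect_equal(as.numeric(s), c(2, 2, 7.3))

  # zero-noise finite differences equal the slopes on each side
  hp2 <- hinge_params(60, -0.1, 0.4, 5)
  v <- hinge_value(hp2, 50:70)
  expect_equal(unique(round(diff(v[1:10]), 12)), -0.1)
  expect_equal(unique(round(diff(v[12:21]), 12)), 0.4)
})

test_that("hinge series noise components add in variance", {
  hp <- hinge_params(60, 0, 0, 10, patient_intercept_sd = 0.5,
                     eye_intercept_sd = 0.3, residual_sd = 0.4)
  draws <- with_seed(99, vapply(1:10000, function(i) {
    as.numeric(simulate_hinge_series(hp, 65))
  }, numeric(1)))
  expect_equal(sd(draws), sqrt(0.5^2 + 0.3^2 + 0.4^2), tolerance = 0.05)
})

test_that("rendered atrophy masks hit the target area and grow nested, temporal first", {
  an <- eye_anatomy(c(470, 500), c(870, 500), 11.5, "right")
  dims <- c(1000, 1152)
  empty <- with_seed(5, render_atrophy_mask(an, 0, dims))
  expect_equal(sum(empty), 0)

  field <- with_seed(5, lesion_arrival_field(an, dims))
  m_small <- render_atrophy_mask(an, 8, dims, field = field)
  m_mid <- render_atrophy_mask(an, 30, dims, field = field)
  m_large <- render_atrophy_mask(an, 71.1, dims, field = field)

  # pixel count matches the area arithmetic within 2%
  expect_equal(sum(m_large), 71.1e6 / 11.5^2, tolerance = 0.02)
  expect_equal(attr(m_mid, "area_mm2"), 30, tolerance = 0.02)

  # nestedness under growth
  expect_true(all(m_mid[m_small]))
  expect_true(all(m_large[m_mid]))

  # temporal origin, nasal expansion
  centroid_x <- function(m) mean(which(m, arr.ind = TRUE)[, 2]) - 1
  expect_lt(centroid_x(m_small), an$fovea_xy[1])
  expect_gt(max(which(m_large, arr.ind = TRUE)[, 2]),
            max(which(m_small, arr.ind = TRUE)[, 2]))

  expect_error(render_atrophy_mask(an, 1e5, dims, field = field), "capacity")
})

test_that("follow-up perturbation plants an exactly recoverable homography", {
  ex <- tiny_exam(image = matrix(runif(240 * 340), 240, 340))
  p0 <- with_seed(3, perturb_followup(ex, max_shift = 0))
  expect_equal(unclass(p0$homography), diag(3), ignore_attr = TRUE)

  pert <- with_seed(3, perturb_followup(ex, max_shift = 8))
  expect_equal(nrow(pert$points), 9)
  # emitted points satisfy the planted homography to numerical precision
  expect_lt(reprojection_error(pert$points, pert$homography), 1e-6)
  # and are non-collinear: the estimator does not hit its degeneracy guard
  expect_s3_class(estimate_projective(pert$points), "homography")
})

test_that("generate_cohort bookkeeping, determinism, and planted stability before onset", {
  cfg <- stats_config(n_patients = 16, eyes_per_patient = 2,
                      visit_ages = list(c(42, 45, 48, 55, 62, 69)), seed = 3)
  coh <- generate_cohort(cfg)
  v <- coh$ledger$visits
  expect_equal(nrow(unique(v[, c("patient", "eye")])), 32)
  expect_equal(nrow(v), 32 * 6)
  expect_equal(nrow(coh$ledger$random_effects), 32 * length(cfg$metrics))

  # byte-identical tabular outputs for identical config
  d1 <- file.path(tempdir(), "coh1"); d2 <- file.path(tempdir(), "coh2")
  write_cohort(coh, d1)
  write_cohort(generate_cohort(cfg), d2)
  for (f in c("clinical.csv", "ledger_visits.csv", "oct_traces.csv")) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)))
  }

  # planted breakpoint at 53.9: no atrophy growth before age 50
  pre <- v$sqrtAA_14mm_true[v$age < 50]
  post <- v$sqrtAA_14mm_true[v$age > 60]
  expect_lt(mean(pre), 0.5)   # baseline noise only (clamped at 0)
  expect_gt(mean(post), 2)    # clear growth past the breakpoint
})

test_that("cohort OCT traces and clinical table realize the planted truths", {
  cfg <- stats_config(n_patients = 3, visit_ages = list(c(55, 60, 65, 72)), seed = 9)
  coh <- generate_cohort(cfg)
  v <- coh$ledger$visits
  for (i in sample(nrow(v), 6)) {
    scan <- coh$oct[[v$exam_id[i]]]
    ez <- ez_width(scan)
    # recovered widths within one a-scan spacing of the planted truth
    if (!ez$fovea_absent) {
      expect_lt(abs(ez$temporal_um - v$EZ_temporal_true[i]),
                cfg$oct_spacing_um + 1e-9)
      expect_lt(abs(ez$nasal_um - v$EZ_nasal_true[i]),
                cfg$oct_spacing_um + 1e-9)
    }
    expect_equal(foveal_thickness(scan, "CRT"), v$CRT_true[i])
    expect_equal(foveal_thickness(scan, "PR_RPE"), v$PR_RPE_true[i])
  }
  bc <- bcva_to_logmar(coh$clinical$bcva)
  expect_lt(max(abs(bc$logmar - v$BCVA_true)), 0.0051)  # 2-decimal rounding
})
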