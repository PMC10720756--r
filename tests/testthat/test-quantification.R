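test_that("area of atrophy counts circle-restricted pixels in mm^2", {
  # 400x400 raster at 40 um/px: the 14 mm circle (r = 175 px) fits
  an <- eye_anatomy(c(200, 200), c(320, 200), 40, "right")
  empty <- matrix(FALSE, 400, 400)
  res0 <- area_of_atrophy(empty, NULL, an, 14)
  expect_equal(res0$area_mm2, 0)
  expect_equal(res0$sqrt_area_mm, 0)
  expect_false(res0$clipped)

  full <- matrix(TRUE, 400, 400)
  res14 <- area_of_atrophy(full, NULL, an, 14)
  expect_equal(res14$area_mm2, pi * 7^2, tolerance = 0.005)
  expect_equal(res14$sqrt_area_mm, sqrt(pi * 7^2), tolerance = 0.0025)

  res6 <- area_of_atrophy(full, NULL, an, 6)
  expect_equal(res6$area_mm2, pi * 3^2, tolerance = 0.005)
  expect_lte(res6$area_mm2, res14$area_mm2)

  # sqrt consistency
  expect_equal(res6$sqrt_area_mm^2, res6$area_mm2)

  # peripapillary exclusion removes its pixels from the count
  ppa <- matrix(FALSE, 400, 400); ppa[190:210, 190:210] <- TRUE
  res_ex <- area_of_atrophy(full, ppa, an, 14)
  expect_equal(res14$area_mm2 - res_ex$area_mm2, sum(ppa) * (40 / 1000)^2)

  # clipped circle warns and flags
  small <- eye_anatomy(c(60, 60), c(180, 60), 40, "right")
  expect_warning(resc <- area_of_atrophy(matrix(TRUE, 120, 240), NULL, small, 14),
                 "beyond the raster")
  expect_true(resc$clipped)
})

test_that("AA(6) <= AA(14) across rendered lesions", {
  an <- tiny_anatomy()
  field <- with_seed(21, lesion_arrival_field(an, c(240, 340)))
  for (target in c(2, 10, 25)) {
    m <- render_atrophy_mask(an, target, c(240, 340), field = field)
    a6 <- suppressWarnings(area_of_atrophy(m, NULL, an, 6))
    a14 <- suppressWarnings(area_of_atrophy(m, NULL, an, 14))
    expect_lte(a6$area_mm2, a14$area_mm2)
  }
})

test_that("EZ width takes the first clear break on each side", {
  sp <- 10
  lat <- seq(-3000, 3000, by = sp)
  # fully intact: censored at the scan edges
  scan <- oct_fovea_scan(lat, rep(TRUE, length(lat)), spacing_um = sp)
  full <- ez_width(scan)
  expect_equal(full$total_um, 6000)
  expect_true(full$censored_temporal && full$censored_nasal)

  # first qualifying breaks at -800 (temporal) and +1500 (nasal)
  intact <- lat > -800 & lat < 1500
  intact[lat >= 2000 & lat <= 2100] <- TRUE  # island beyond the break: ignored
  ez <- ez_width(oct_fovea_scan(lat, intact, spacing_um = sp))
  expect_equal(ez$temporal_um, 800)
  expect_equal(ez$nasal_um, 1500)
  expect_equal(ez$total_um, 2300)
  expect_false(ez$censored_temporal || ez$censored_nasal)

  # single-sample dropout below the break threshold is attenuation, not loss
  intact2 <- rep(TRUE, length(lat))
  intact2[lat == 700] <- FALSE
  ez2 <- ez_width(oct_fovea_scan(lat, intact2, spacing_um = sp),
                  min_break_extent = 2 * sp)
  expect_equal(ez2$nasal_um, 3000)
  expect_true(ez2$censored_nasal)
  # but it does qualify if the threshold is a single sample
  ez3 <- ez_width(oct_fovea_scan(lat, intact2, spacing_um = sp),
                  min_break_extent = sp)
  expect_equal(ez3$nasal_um, 700)

  # absent at the fovea: all widths zero
  ez4 <- ez_width(oct_fovea_scan(lat, rep(FALSE, length(lat)), spacing_um = sp))
  expect_equal(c(ez4$temporal_um, ez4$nasal_um, ez4$total_um), c(0, 0, 0))
  expect_true(ez4$fovea_absent)

  # total is exactly the sum of the sides
  expect_equal(ez$total_um, ez$temporal_um + ez$nasal_um)

  expect_error(oct_fovea_scan(seq(100, 500, 10), rep(TRUE, 41)), "not sampled")
})

test_that("foveal thickness subtracts boundary heights vertically", {
  sp <- 10; lat <- seq(-300, 300, by = sp)
  scan <- oct_fovea_scan(lat, rep(TRUE, length(lat)),
                         boundaries_um = c(ILM = 0, ELM = 133.5, RPE_post = 226.5),
                         spacing_um = sp)
  expect_equal(foveal_thickness(scan, "CRT"), 226.5)
  expect_equal(foveal_thickness(scan, "PR_RPE"), 93)

  missing_elm <- oct_fovea_scan(lat, rep(TRUE, length(lat)),
                                boundaries_um = c(ILM = 0, RPE_post = 226.5),
                                spacing_um = sp)
  expect_warning(res <- foveal_thickness(missing_elm, "PR_RPE"), "missing boundary")
  expect_true(is.na(res))
  expect_equal(foveal_thickness(missing_elm, "CRT"), 226.5)
})

test_that("BCVA conversion maps qualitative codes and passes numerics through", {
  out <- bcva_to_logmar(c("CF", "HM", "LP", "NLP"))
  expect_equal(out$logmar, c(2.6, 2.7, 2.8, 2.9))
  expect_true(all(out$end_stage))

  mixed <- bcva_to_logmar(c("0.30", "-0.08", "cf", " NLP "))
  expect_equal(mixed$logmar, c(0.30, -0.08, 2.6, 2.9))
  expect_equal(mixed$end_stage, c(FALSE, FALSE, TRUE, TRUE))

  num <- bcva_to_logmar(c(0.3, 1.4))
  expect_equal(num$logmar, c(0.3, 1.4))
  expect_false(any(num$end_stage))

  expect_error(bcva_to_logmar(c("0.3", "PLX")), "unrecognized")
})
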