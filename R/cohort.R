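#' Default hinge parameters for the standard LORD metric panel
#'
#' Breakpoints and post-breakpoint slopes follow the published natural
#' history of C1QTNF5 LORD (stable until the inflection age, then linear
#' change); the variance components are generator defaults chosen to give
#' field-realistic between-patient spread and visit noise — they are free
#' parameters of the simulator, not published quantities.
#'
#' @return Named list of [hinge_params()] for `sqrtAA_14mm` (mm),
#'   `sqrtAA_6mm` (mm), `EZ_total` (µm), `CRT` (µm), `PR_RPE` (µm),
#'   `BCVA_logMAR` (LogMAR).
#' @export
default_metric_params <- function() {
  list(
    sqrtAA_14mm = hinge_params(53.9, 0, 0.53, 0, 0.5, 0.2, 0.15),
    sqrtAA_6mm  = hinge_params(56.3, 0, 0.24, 0, 0.25, 0.1, 0.1),
    EZ_total    = hinge_params(50.8, 0, -257, 5800, 300, 120, 150),
    CRT         = hinge_params(62.3, 0, -4.7, 240, 20, 8, 8),
    PR_RPE      = hinge_params(60.0, 0, -3.8, 100, 10, 4, 5),
    BCVA_logMAR = hinge_params(70.3, 0, 0.05, 0.1, 0.1, 0.05, 0.05)
  )
}

#' Configuration for the synthetic longitudinal cohort
#'
#' Defines the study conditions the generator emulates: cohort shape
#' (patients, eyes, visit schedules with a median follow-up of ~5 years),
#' hinge trajectory parameters per metric, interocular sharing, and the
#' imaging geometry (pixel scale, fovea-disc distance variability, raster
#' size).
#'
#' @param n_patients Number of patients.
#' @param eyes_per_patient 1 or 2.
#' @param visit_ages `NULL` to sample per-patient schedules, or a list of
#'   strictly increasing age vectors (recycled per patient).
#' @param metrics Named list of [hinge_params()]; defaults to
#'   [default_metric_params()].
#' @param interocular_latent_share Fraction in `[0, 1]` of residual
#'   variance shared between fellow eyes (on top of the shared patient
#'   intercept and trajectory); see [latent_share_for_r()].
#' @param image_size Raster `c(rows, cols)` in px.
#' @param pixel_scale_range Lateral scale range, µm/px.
#' @param fovea_disc_distance_range Fovea-ONH distance range, µm.
#' @param peripapillary_fraction Fraction of eyes given a peripapillary
#'   atrophy annulus.
#' @param max_shift Maximum planted misregistration of follow-up images, px.
#' @param n_control_points Control-point pairs emitted per follow-up.
#' @param oct_half_extent_um,oct_spacing_um OCT trace geometry (µm).
#' @param render_images Render FAF rasters and masks (disable for
#'   statistics-only cohorts).
#' @param seed Master seed; fully determines all outputs.
#' @return Object of class `cohort_config`.
#' @export
cohort_config <- function(n_patients = 16, eyes_per_patient = 2,
                          visit_ages = NULL,
                          metrics = default_metric_params(),
                          interocular_latent_share = 0.9,
                          image_size = c(448, 576),
                          pixel_scale_range = c(34, 40),
                          fovea_disc_distance_range = c(4400, 4900),
                          peripapillary_fraction = 0.3,
                          max_shift = 10, n_control_points = 9,
                          oct_half_extent_um = 3000, oct_spacing_um = 12,
                          render_images = TRUE, seed = 1L) {
  stopifnot(n_patients >= 1, eyes_per_patient %in% c(1L, 2L),
            interocular_latent_share >= 0, interocular_latent_share <= 1,
            length(image_size) == 2, all(image_size > 0),
            diff(pixel_scale_range) >= 0, all(pixel_scale_range > 0),
            diff(fovea_disc_distance_range) >= 0,
            peripapillary_fraction >= 0, peripapillary_fraction <= 1,
            max_shift >= 0, n_control_points >= 4,
            oct_half_extent_um > 0, oct_spacing_um > 0)
  if (!is.null(visit_ages)) {
    lapply(visit_ages, function(a) {
      if (is.unsorted(a, strictly = TRUE)) {
        stop("visit ages must be strictly increasing", call. = FALSE)
      }
    })
  }
  stopifnot(all(vapply(metrics, inherits, logical(1), "hinge_params")))
  structure(
    list(n_patients = as.integer(n_patients),
         eyes_per_patient = as.integer(eyes_per_patient),
         visit_ages = visit_ages, metrics = metrics,
         interocular_latent_share = interocular_latent_share,
         image_size = as.integer(image_size),
         pixel_scale_range = pixel_scale_range,
         fovea_disc_distance_range = fovea_disc_distance_range,
         peripapillary_fraction = peripapillary_fraction,
         max_shift = max_shift, n_control_points = as.integer(n_control_points),
         oct_half_extent_um = oct_half_extent_um, oct_spacing_um = oct_spacing_um,
         render_images = isTRUE(render_images), seed = as.integer(seed)),
    class = "cohort_config"
  )
}

# Snap a fovea-disc pixel distance to the nearest integer distance for
# which the 20-superpixel rule places the ONH exactly in column 20
# (n = round(dx/20) integer superpixels; see build_grid). The adjustment
# is at most a few pixels (tens of micrometres), anatomically negligible.
snap_fovea_disc_dx <- function(dx_px) {
  dx0 <- round(dx_px)
  valid <- function(d) {
    n <- max(1, round_half_up(d / 20))
    round_half_up(d / n) == 20
  }
  for (off in 0:12) {
    for (d in unique(c(dx0 + off, dx0 - off))) {
      if (d >= 20 && valid(d)) return(as.integer(d))
    }
  }
  stop("no 20-superpixel-compatible fovea-disc distance near ", dx0, call. = FALSE)
}

#' Generate one eye's anatomy
#'
#' Samples pixel scale and fovea-disc distance from the configured ranges
#' (reproducibly from the config seed and the patient/eye identity), snaps
#' the pixel distance so the 20-superpixel grid places the ONH exactly at
#' index (20, 0), and positions the landmarks in the raster. Right eyes
#' have the ONH nasal (at larger `x`) of the fovea; left eyes are
#' generated mirrored.
#'
#' @param config A [cohort_config()].
#' @param patient Patient index or id string.
#' @param eye `"right"` or `"left"`.
#' @return An [eye_anatomy()].
#' @export
generate_anatomy <- function(config, patient, eye = c("right", "left")) {
  eye <- match.arg(eye)
  stopifnot(inherits(config, "cohort_config"))
  with_seed(substream_seed(config$seed, patient, eye, "anatomy"), {
    scale <- runif(1, config$pixel_scale_range[1], config$pixel_scale_range[2])
    fd_um <- runif(1, config$fovea_disc_distance_range[1],
                   config$fovea_disc_distance_range[2])
    dx <- fd_um / scale
    if (dx < 20) {
      stop("invalid config: fovea-disc distance not representable at this pixel scale",
           call. = FALSE)
    }
    h <- config$image_size[1]; w <- config$image_size[2]
    if (w < 2 * dx) {
      stop("invalid config: image width below twice the fovea-disc pixel distance",
           call. = FALSE)
    }
    dx <- snap_fovea_disc_dx(dx)
    fx_right <- 0.40 * (w - 1) + runif(1, -8, 8)
    fy <- 0.5 * (h - 1) + runif(1, -8, 8)
    onh_dy <- runif(1, -0.06, 0.06) * dx   # ONH slightly off the fovea axis
    if (eye == "right") {
      fovea <- c(fx_right, fy); onh <- c(fx_right + dx, fy + onh_dy)
    } else {
      fx <- (w - 1) - fx_right
      fovea <- c(fx, fy); onh <- c(fx - dx, fy + onh_dy)
    }
    if (any(onh < 0) || onh[1] > w - 1 || onh[2] > h - 1) {
      stop("invalid config: ONH falls outside the raster", call. = FALSE)
    }
    eye_anatomy(fovea, onh, scale, eye)
  })
}

sample_visit_ages <- function(config, patient) {
  if (!is.null(config$visit_ages)) {
    idx <- (as.integer(patient) - 1L) %% length(config$visit_ages) + 1L
    return(config$visit_ages[[idx]])
  }
  with_seed(substream_seed(config$seed, patient, "ages"), {
    baseline <- min(max(rnorm(1, 62, 5), 50), 72)
    n_visits <- sample(2:6, 1)
    gaps <- runif(n_visits - 1, 0.8, 1.8)
    round(baseline + c(0, cumsum(gaps)), 2)
  })
}

#' Generate a fully synthetic longitudinal LORD cohort with ground truth
#'
#' Produces, for every patient/eye/visit: hinge-model metric series with
#' patient and eye random intercepts and interocular sharing, FAF exams
#' with scalloped atrophy masks whose total area equals the square of the
#' planted sqrt-area trajectory (plus a peripapillary annulus in a
#' configured fraction of eyes), planted projective misregistration of
#' follow-up exams with exact control points, OCT foveal traces realizing
#' the EZ-width and thickness truths, and a clinical BCVA table with
#' end-stage qualitative codes. Every generated quantity is recorded in
#' the ground-truth ledger.
#'
#' All randomness derives from `config$seed` through per-eye substreams,
#' so identical configurations reproduce the cohort bit-for-bit.
#'
#' @param config A [cohort_config()].
#' @return Object of class `lord_cohort`: list with `exams` (list of
#'   entries: `exam`, `points`, `planted_h`, `exam_id`, `is_baseline`),
#'   `oct` (named list of [oct_fovea_scan()]), `clinical` (data.frame
#'   `patient, eye, age, bcva`), and `ledger` (list of data.frames
#'   `visits`, `random_effects`, `homographies`).
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  eyes <- c("right", "left")[seq_len(config$eyes_per_patient)]
  metrics <- config$metrics
  lambda <- config$interocular_latent_share

  exams <- list(); oct <- list()
  visits_rows <- list(); re_rows <- list(); hom_rows <- list(); clin_rows <- list()

  for (p in seq_len(config$n_patients)) {
    ages <- sample_visit_ages(config, p)
    shared <- lapply(names(metrics), function(m) {
      with_seed(substream_seed(config$seed, p, "shared", m),
                shared_hinge_component(metrics[[m]], ages))
    })
    names(shared) <- names(metrics)
    for (e in eyes) {
      series <- list(); u_pat <- list(); u_eye <- list()
      for (m in names(metrics)) {
        s <- with_seed(substream_seed(config$seed, p, e, m),
                       simulate_hinge_series(metrics[[m]], ages,
                                             shared = shared[[m]],
                                             latent_share = lambda))
        u_pat[[m]] <- attr(s, "u_patient"); u_eye[[m]] <- attr(s, "u_eye")
        series[[m]] <- as.numeric(s)
      }
      # physical clamps on realized values
      series$sqrtAA_14mm <- cummax(pmax(series$sqrtAA_14mm, 0))  # atrophy never regresses
      series$sqrtAA_6mm <- cummax(pmax(series$sqrtAA_6mm, 0))
      extent <- 2 * config$oct_half_extent_um
      series$EZ_total <- pmin(pmax(series$EZ_total, 0), extent)
      series$CRT <- pmax(series$CRT, 40)
      series$PR_RPE <- pmax(series$PR_RPE, 0)
      series$BCVA_logMAR <- pmax(series$BCVA_logMAR, -0.3)

      anatomy <- generate_anatomy(config, p, e)
      has_ppa <- with_seed(substream_seed(config$seed, p, e, "ppa"),
                           runif(1) < config$peripapillary_fraction)
      dims <- config$image_size
      field <- NULL; ppa <- NULL; baseline_exam <- NULL
      if (config$render_images) {
        field <- with_seed(substream_seed(config$seed, p, e, "lesion"),
                           lesion_arrival_field(anatomy, dims))
        ppa <- if (has_ppa) render_peripapillary_mask(anatomy, dims) else NULL
      }

      # temporal-first EZ split: the temporal half-width erodes before the
      # nasal one, with mild jitter
      half <- config$oct_half_extent_um
      loss <- extent - series$EZ_total
      jit <- with_seed(substream_seed(config$seed, p, e, "ezsplit"),
                       rnorm(length(ages), 0, 0.03 * half))
      ez_t <- pmin(pmax(half - loss + jit, 0), half)
      ez_t <- pmin(ez_t, series$EZ_total)
      ez_n <- series$EZ_total - ez_t

      for (v in seq_along(ages)) {
        exam_id <- sprintf("P%02d_%s_V%d", p, substr(e, 1, 1), v)
        aa_real_14 <- NA_real_; aa_real_6 <- NA_real_
        if (config$render_images) {
          target <- series$sqrtAA_14mm[v]^2
          mask <- render_atrophy_mask(anatomy, target, dims, field = field)
          img <- render_faf_image(mask, ppa, anatomy, dims,
                                  seed = substream_seed(config$seed, p, e, "img"))
          exam <- faf_exam(img, mask, ppa, anatomy, sprintf("P%02d", p), e,
                           ages[v], "55")
          # clipping of the 14 mm circle on small rasters is routine here;
          # the analysis path re-measures and flags it itself
          aa_real_14 <- suppressWarnings(area_of_atrophy(mask, ppa, anatomy, 14)$area_mm2)
          aa_real_6 <- suppressWarnings(area_of_atrophy(mask, ppa, anatomy, 6)$area_mm2)
          if (v == 1) {
            exams[[exam_id]] <- list(exam = exam, points = NULL, planted_h = NULL,
                                     exam_id = exam_id, is_baseline = TRUE)
            hom_rows[[exam_id]] <- data.frame(exam_id = exam_id,
                                              t(as.numeric(diag(3))))
          } else {
            pert <- with_seed(substream_seed(config$seed, p, e, v, "perturb"),
                              perturb_followup(exam, config$max_shift,
                                               config$n_control_points))
            exams[[exam_id]] <- list(exam = pert$exam, points = pert$points,
                                     planted_h = pert$homography,
                                     exam_id = exam_id, is_baseline = FALSE)
            hom_rows[[exam_id]] <- data.frame(exam_id = exam_id,
                                              t(as.numeric(pert$homography)))
          }
        }
        oct[[exam_id]] <- synth_oct_scan(ez_t[v], ez_n[v], series$CRT[v],
                                         series$PR_RPE[v], half,
                                         config$oct_spacing_um,
                                         seed = substream_seed(config$seed, p, e, v, "oct"))
        visits_rows[[exam_id]] <- data.frame(
          patient = sprintf("P%02d", p), eye = e, age = ages[v], exam_id = exam_id,
          sqrtAA_14mm_true = series$sqrtAA_14mm[v],
          sqrtAA_6mm_true = series$sqrtAA_6mm[v],
          AA_total_target_mm2 = series$sqrtAA_14mm[v]^2,
          AA_14mm_realized_mm2 = aa_real_14, AA_6mm_realized_mm2 = aa_real_6,
          EZ_total_true = series$EZ_total[v], EZ_temporal_true = ez_t[v],
          EZ_nasal_true = ez_n[v],
          CRT_true = series$CRT[v], PR_RPE_true = series$PR_RPE[v],
          BCVA_true = series$BCVA_logMAR[v], has_ppa = has_ppa
        )
        clin_rows[[exam_id]] <- data.frame(
          patient = sprintf("P%02d", p), eye = e, age = ages[v],
          bcva = format_bcva(series$BCVA_logMAR[v])
        )
      }
      re_rows[[paste(p, e)]] <- data.frame(
        patient = sprintf("P%02d", p), eye = e,
        metric = names(metrics),
        u_patient = unlist(u_pat), u_eye = unlist(u_eye), row.names = NULL
      )
    }
  }

  structure(
    list(exams = exams, oct = oct,
         clinical = do.call(rbind, c(clin_rows, list(make.row.names = FALSE))),
         ledger = list(
           visits = do.call(rbind, c(visits_rows, list(make.row.names = FALSE))),
           random_effects = do.call(rbind, c(re_rows, list(make.row.names = FALSE))),
           homographies = if (length(hom_rows)) {
             do.call(rbind, c(hom_rows, list(make.row.names = FALSE)))
           } else NULL
         ),
         config = config),
    class = "lord_cohort"
  )
}

#' @export
print.lord_cohort <- function(x, ...) {
  v <- x$ledger$visits
  cat(sprintf("<lord_cohort> %d patients, %d eye series, %d exams | images: %s\n",
              length(unique(v$patient)),
              nrow(unique(v[, c("patient", "eye")])), nrow(v),
              if (x$config$render_images) "rendered" else "not rendered"))
  invisible(x)
}

# Schematic FAF intensity raster: bright background with hypo-AF atrophy
# and mildly dark peripapillary ring; smooth illumination gradient plus a
# little grain so registration has texture to work with.
render_faf_image <- function(mask, ppa, anatomy, dims, seed) {
  h <- dims[1]; w <- dims[2]
  with_seed(seed, {
    gx <- matrix(rep(seq(-0.5, 0.5, length.out = w), each = h), h, w)
    gy <- matrix(rep(seq(-0.5, 0.5, length.out = h), times = w), h, w)
    img <- 0.62 - 0.10 * (gx^2 + gy^2) + matrix(rnorm(h * w, 0, 0.015), h, w)
    img[mask] <- img[mask] * 0.25
    if (!is.null(ppa)) img[ppa] <- img[ppa] * 0.45
    pmin(pmax(img, 0), 1)
  })
}

# EZ-integrity trace and boundary heights realizing the planted truths;
# occasionally inserts a single-sample dropout (signal attenuation) that
# must NOT count as clear EZ loss.
synth_oct_scan <- function(ez_temporal, ez_nasal, crt, pr_rpe, half_extent,
                           spacing, seed) {
  lateral <- seq(-half_extent, half_extent, by = spacing)
  intact <- lateral >= -ez_temporal & lateral <= ez_nasal
  if (ez_temporal == 0 && ez_nasal == 0) intact[] <- FALSE
  with_seed(seed, {
    inside <- which(intact)
    inside <- inside[abs(lateral[inside]) > 4 * spacing]  # keep the fovea clean
    if (length(inside) > 3 && runif(1) < 0.3) {
      intact[sample(inside, 1)] <- FALSE                  # attenuation artifact
    }
  })
  oct_fovea_scan(lateral, intact,
                 boundaries_um = c(ILM = 300 - crt, ELM = 300 - pr_rpe,
                                   RPE_post = 300),
                 spacing_um = spacing)
}

format_bcva <- function(logmar) {
  if (logmar >= 2.85) "NLP"
  else if (logmar >= 2.75) "LP"
  else if (logmar >= 2.65) "HM"
  else if (logmar >= 2.55) "CF"
  else sprintf("%.2f", logmar)
}

#' Write a generated cohort to disk
#'
#' FAF images and masks as single-channel PNG with JSON sidecars, control
#' points and planted homographies as CSV, the clinical table and ledger
#' as CSV. Output is byte-identical for identical configurations.
#'
#' @param cohort A [generate_cohort()] result.
#' @param dir Output directory.
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "lord_cohort"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(cohort$clinical, file.path(dir, "clinical.csv"), row.names = FALSE)
  utils::write.csv(cohort$ledger$visits, file.path(dir, "ledger_visits.csv"),
                   row.names = FALSE)
  utils::write.csv(cohort$ledger$random_effects,
                   file.path(dir, "ledger_random_effects.csv"), row.names = FALSE)
  if (!is.null(cohort$ledger$homographies)) {
    utils::write.csv(cohort$ledger$homographies,
                     file.path(dir, "ledger_homographies.csv"), row.names = FALSE)
  }
  oct_df <- do.call(rbind, lapply(names(cohort$oct), function(id) {
    s <- cohort$oct[[id]]
    data.frame(exam_id = id, lateral_um = s$lateral_um, ez_intact = s$ez_intact,
               ILM = s$boundaries_um[["ILM"]], ELM = s$boundaries_um[["ELM"]],
               RPE_post = s$boundaries_um[["RPE_post"]])
  }))
  utils::write.csv(oct_df, file.path(dir, "oct_traces.csv"), row.names = FALSE)
  if (cohort$config$render_images) {
    img_dir <- file.path(dir, "exams")
    for (entry in cohort$exams) {
      write_exam(entry$exam, img_dir, entry$exam_id)
      if (!is.null(entry$points)) {
        write_control_points(entry$points,
                             file.path(img_dir, paste0(entry$exam_id, "_points.csv")))
      }
    }
  }
  invisible(dir)
}
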