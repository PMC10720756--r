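#' Pipeline configuration
#'
#' Bundles the thresholds and options of an end-to-end run. All values are
#' plain scalars, so a config round-trips through JSON unchanged.
#'
#' @param cohort A [cohort_config()] for the simulate stage.
#' @param out_dir Output directory for CSV artifacts.
#' @param theta Superpixel atrophic threshold (inclusive).
#' @param min_break_extent_factor EZ break threshold as a multiple of the
#'   a-scan spacing.
#' @param min_exams Spatial censoring threshold.
#' @param min_points Minimum control points for registration.
#' @param stratum_breaks Age stratum boundaries, years.
#' @param circle_diameters_mm Circle diameters for area of atrophy.
#' @param n_boot Bootstrap replicates for hinge CIs.
#' @param hinge_grid_step Breakpoint grid step, years.
#' @param seed Seed for the analysis stages (bootstrap).
#' @return Object of class `run_config`.
#' @export
run_config <- function(cohort = cohort_config(), out_dir = tempfile("lordprog_run_"),
                       theta = 0.5, min_break_extent_factor = 2,
                       min_exams = 4, min_points = 9,
                       stratum_breaks = c(55, 60, 65, 70),
                       circle_diameters_mm = c(6, 14),
                       n_boot = 200, hinge_grid_step = 0.1, seed = 1L) {
  stopifnot(inherits(cohort, "cohort_config"),
            theta > 0, theta <= 1, min_break_extent_factor > 0,
            min_exams >= 1, min_points >= 4, all(circle_diameters_mm > 0),
            n_boot >= 0, hinge_grid_step > 0)
  structure(list(cohort = cohort, out_dir = out_dir, theta = theta,
                 min_break_extent_factor = min_break_extent_factor,
                 min_exams = min_exams, min_points = min_points,
                 stratum_breaks = stratum_breaks,
                 circle_diameters_mm = circle_diameters_mm,
                 n_boot = n_boot, hinge_grid_step = hinge_grid_step,
                 seed = as.integer(seed)),
            class = "run_config")
}

#' Run the full analysis pipeline on a synthetic cohort
#'
#' Stages: simulate -> flip to right-eye format -> register follow-ups to
#' baseline from control points -> shear-align and map superpixel atrophy
#' -> quantify scalar metrics -> fit progression models (mixed model,
#' hinge, interocular repeated-measures correlation) -> age-stratified
#' spatial prevalence -> write CSV reports and a plain-text log. Re-runs
#' with an identical config produce identical tabular outputs.
#'
#' @param config A [run_config()].
#' @param cohort Optionally a pre-generated [generate_cohort()] result
#'   (must match `config$cohort`); generated when `NULL`.
#' @return Invisibly, a list with `metrics` (long metric table), `fits`
#'   (model summary table), `strata`, `maps`, `registration` (per-exam RMS
#'   reprojection errors), and `log` (character vector).
#' @export
run_pipeline <- function(config = run_config(), cohort = NULL) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  log_lines <- character()
  say <- function(fmt, ...) {
    line <- sprintf(fmt, ...)
    log_lines <<- c(log_lines, line)
    message(line)
  }

  say("stage simulate: seed %d, %d patients x %d eyes", config$cohort$seed,
      config$cohort$n_patients, config$cohort$eyes_per_patient)
  if (is.null(cohort)) cohort <- generate_cohort(config$cohort)
  ledger <- cohort$ledger$visits
  say("  %d exams in ledger", nrow(ledger))

  metrics_rows <- list(); map_list <- list(); map_ages <- numeric()
  reg_rows <- list()

  if (config$cohort$render_images) {
    # group exams by eye series; baseline first
    series_ids <- unique(ledger[, c("patient", "eye")])
    for (i in seq_len(nrow(series_ids))) {
      rows <- ledger[ledger$patient == series_ids$patient[i] &
                       ledger$eye == series_ids$eye[i], ]
      rows <- rows[order(rows$age), ]
      for (v in seq_len(nrow(rows))) {
        entry <- cohort$exams[[rows$exam_id[v]]]
        exam <- entry$exam
        if (!entry$is_baseline) {
          if (nrow(entry$points) < config$min_points) {
            stop(sprintf("stage register: exam %s has %d control points, %d required",
                         entry$exam_id, nrow(entry$points), config$min_points),
                 call. = FALSE)
          }
          h_est <- estimate_projective(entry$points, min_points = config$min_points)
          rms <- reprojection_error(entry$points, h_est)
          reg_rows[[entry$exam_id]] <- data.frame(exam_id = entry$exam_id,
                                                  rms_px = rms)
          exam$image <- apply_transform(exam$image, h_est, "image")
          exam$atrophy_mask <- apply_transform(exam$atrophy_mask, h_est, "mask")
          exam$peripapillary_mask <- apply_transform(exam$peripapillary_mask,
                                                     h_est, "mask")
          # after registration the exam lives in the baseline frame
          base_entry <- cohort$exams[[rows$exam_id[1]]]
          exam$anatomy <- base_entry$exam$anatomy
        }
        exam <- flip_to_right_eye(exam)
        for (d in config$circle_diameters_mm) {
          aa <- suppressWarnings(
            area_of_atrophy(exam$atrophy_mask, exam$peripapillary_mask,
                            exam$anatomy, d))
          metrics_rows[[length(metrics_rows) + 1L]] <- data.frame(
            patient = rows$patient[v], eye = rows$eye[v], age = rows$age[v],
            metric = sprintf("sqrtAA_%dmm", d), value = aa$sqrt_area_mm,
            units = "mm", flag = if (aa$clipped) "clipped" else "")
        }
        sh <- shear_align(exam$atrophy_mask, exam$anatomy)
        sh_ppa <- shear_align(exam$peripapillary_mask, exam$anatomy)
        grid <- build_grid(sh$anatomy)
        amap <- compute_atrophy_map(sh$mask, sh_ppa$mask, grid,
                                    theta = config$theta,
                                    exam_id = rows$exam_id[v],
                                    age_years = rows$age[v])
        map_list[[length(map_list) + 1L]] <- amap
        map_ages <- c(map_ages, rows$age[v])
      }
    }
    say("stage register: %d follow-up exams aligned, max RMS %.2g px",
        length(reg_rows),
        if (length(reg_rows)) max(vapply(reg_rows, function(r) r$rms_px, 1)) else 0)
    say("stage map: %d superpixel maps", length(map_list))
  } else {
    say("stage register/map: skipped (images not rendered)")
  }

  # OCT metrics
  for (id in names(cohort$oct)) {
    row <- ledger[ledger$exam_id == id, ]
    scan <- cohort$oct[[id]]
    ez <- ez_width(scan, min_break_extent = config$min_break_extent_factor *
                     scan$spacing_um)
    metrics_rows[[length(metrics_rows) + 1L]] <- data.frame(
      patient = rep(row$patient, 4), eye = rep(row$eye, 4), age = rep(row$age, 4),
      metric = c("EZ_total", "EZ_temporal", "EZ_nasal", "CRT"),
      value = c(ez$total_um, ez$temporal_um, ez$nasal_um,
                foveal_thickness(scan, "CRT")),
      units = c("um", "um", "um", "um"),
      flag = c(paste0(if (ez$censored_temporal) "censT" else "",
                      if (ez$censored_nasal) "censN" else ""), "", "", ""))
    metrics_rows[[length(metrics_rows) + 1L]] <- data.frame(
      patient = row$patient, eye = row$eye, age = row$age, metric = "PR_RPE",
      value = foveal_thickness(scan, "PR_RPE"), units = "um", flag = "")
  }
  # BCVA
  bc <- bcva_to_logmar(cohort$clinical$bcva)
  metrics_rows[[length(metrics_rows) + 1L]] <- data.frame(
    patient = cohort$clinical$patient, eye = cohort$clinical$eye,
    age = cohort$clinical$age, metric = "BCVA_logMAR", value = bc$logmar,
    units = "LogMAR", flag = ifelse(bc$end_stage, "end_stage", ""))
  metrics <- do.call(rbind, c(metrics_rows, list(make.row.names = FALSE)))
  say("stage quantify: %d metric records", nrow(metrics))

  # progression fits per metric
  fit_metrics <- intersect(c("sqrtAA_6mm", "sqrtAA_14mm", "EZ_total", "CRT",
                             "PR_RPE", "BCVA_logMAR"), unique(metrics$metric))
  fits <- list()
  for (m in fit_metrics) {
    df <- metrics[metrics$metric == m, ]
    if (m == "BCVA_logMAR") {
      df$end_stage <- df$flag == "end_stage"
      df <- filter_endstage_bcva(df)
    }
    lf <- tryCatch(fit_lmm(df), error = function(e) NULL)
    hf <- tryCatch(withr_seed_boot(config$seed, df, config$hinge_grid_step,
                                   config$n_boot),
                   error = function(e) NULL, warning = function(w) NULL)
    paired <- pair_eyes(df)
    rc <- if (!is.null(paired)) {
      tryCatch(suppressWarnings(
        rm_correlation(paired$right, paired$left, paired$patient)),
        error = function(e) NULL)
    } else NULL
    fits[[m]] <- data.frame(
      metric = m,
      n_obs = if (is.null(lf)) NA else lf$n_obs,
      n_eyes = if (is.null(lf)) NA else lf$n_eyes,
      n_patients = if (is.null(lf)) NA else lf$n_patients,
      slope = if (is.null(lf)) NA else lf$slope,
      slope_lo = if (is.null(lf)) NA else lf$slope_ci[1],
      slope_hi = if (is.null(lf)) NA else lf$slope_ci[2],
      chi2 = if (is.null(lf)) NA else lf$chi2,
      p_raw = if (is.null(lf)) NA else lf$p,
      psi = if (is.null(hf)) NA else hf$psi,
      psi_lo = if (is.null(hf)) NA else hf$psi_ci[1],
      psi_hi = if (is.null(hf)) NA else hf$psi_ci[2],
      r_interocular = if (is.null(rc)) NA else rc$r,
      r_lo = if (is.null(rc)) NA else rc$ci[1],
      r_hi = if (is.null(rc)) NA else rc$ci[2])
  }
  fits <- do.call(rbind, c(fits, list(make.row.names = FALSE)))
  fits$p_bonferroni <- bonferroni_adjust(ifelse(is.na(fits$p_raw), 1, fits$p_raw),
                                         family_size = nrow(fits))
  say("stage fit: %d metrics modelled", nrow(fits))

  strata <- NULL
  if (length(map_list)) {
    strata <- stratify_and_prevalence(map_list, map_ages,
                                      breaks = config$stratum_breaks,
                                      min_exams = config$min_exams)
    export_heatmaps(strata, file.path(config$out_dir, "strata.csv"))
    say("stage spatial: %d stratum-locations (%d censored)", nrow(strata),
        sum(strata$censored))
  }

  utils::write.csv(metrics, file.path(config$out_dir, "metrics.csv"),
                   row.names = FALSE)
  utils::write.csv(fits, file.path(config$out_dir, "fits.csv"), row.names = FALSE)
  if (length(reg_rows)) {
    utils::write.csv(do.call(rbind, c(reg_rows, list(make.row.names = FALSE))),
                     file.path(config$out_dir, "registration.csv"),
                     row.names = FALSE)
  }
  writeLines(log_lines, file.path(config$out_dir, "run_log.txt"))
  say("stage report: artifacts in %s", config$out_dir)

  invisible(list(metrics = metrics, fits = fits, strata = strata,
                 maps = map_list,
                 registration = if (length(reg_rows)) {
                   do.call(rbind, c(reg_rows, list(make.row.names = FALSE)))
                 } else NULL,
                 log = log_lines))
}

withr_seed_boot <- function(seed, df, grid_step, n_boot) {
  with_seed(seed, fit_hinge(df, grid_step = grid_step, n_boot = n_boot))
}

# Align fellow-eye series on (patient, age) for interocular correlation.
pair_eyes <- function(df) {
  r <- df[df$eye == "right", c("patient", "age", "value")]
  l <- df[df$eye == "left", c("patient", "age", "value")]
  if (!nrow(r) || !nrow(l)) return(NULL)
  m <- merge(r, l, by = c("patient", "age"), suffixes = c("_r", "_l"))
  if (nrow(m) < 6) return(NULL)
  list(right = m$value_r, left = m$value_l, patient = m$patient)
}
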