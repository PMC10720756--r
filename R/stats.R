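#' Linear mixed model for age-related progression of one metric
#'
#' Fits `value ~ age` with random intercepts for patient and for eye
#' within patient (REML), the structure used for longitudinal ophthalmic
#' series including both eyes. Only eyes with two or more visits enter the
#' fit. The age effect is tested by a likelihood-ratio test against the
#' intercept-only null, both refit by full maximum likelihood (1 df). The
#' 95% CI on the slope is Wald. `r2_marginal` is the fixed-effects
#' (marginal) variance explained:
#' `var(X beta) / (var(X beta) + sum(variance components) + sigma^2)`.
#'
#' @param records data.frame with columns `value`, `age`, `patient`, `eye`
#'   (and optionally `metric` when `metric` is given).
#' @param metric Optional metric name to filter a long-format table on.
#' @param crossed Use crossed random intercepts `(1|patient) + (1|eye)`
#'   (eye as a laterality label) instead of the default nested
#'   eye-within-patient structure.
#' @param lrt Perform the likelihood-ratio test of the age effect (two
#'   extra ML fits); disable for speed in resampling loops (`chi2`/`p`
#'   are then `NA`).
#' @param conf Confidence level for the Wald CI.
#' @return Object of class `lmm_fit`: slope and CI (units/year),
#'   intercept, variance components, LRT chi-square and p, marginal R2,
#'   sample sizes, and the underlying `lmerMod`.
#' @export
fit_lmm <- function(records, metric = NULL, crossed = FALSE, lrt = TRUE,
                    conf = 0.95) {
  df <- prepare_records(records, metric)
  # inclusion rule: eyes with >= 2 visits
  key <- interaction(df$patient, df$eye, drop = TRUE)
  visits <- table(key)
  df <- df[key %in% names(visits)[visits >= 2], , drop = FALSE]
  if (length(unique(df$age)) < 3) {
    stop("underdetermined: fewer than 3 distinct ages after inclusion filtering",
         call. = FALSE)
  }
  df$patient <- factor(df$patient)
  df$eye_unit <- if (crossed) factor(df$eye) else interaction(df$patient, df$eye, drop = TRUE)
  form <- value ~ age + (1 | patient) + (1 | eye_unit)
  fit <- suppressMessages(lme4::lmer(form, data = df, REML = TRUE))
  fe <- lme4::fixef(fit)
  se <- sqrt(diag(as.matrix(vcov(fit))))["age"]
  z <- qnorm(1 - (1 - conf) / 2)
  vc <- as.data.frame(lme4::VarCorr(fit))
  get_vc <- function(g) {
    i <- vc$grp == g & is.na(vc$var2)
    if (any(i)) vc$vcov[i][1] else 0
  }
  v_pat <- get_vc("patient"); v_eye <- get_vc("eye_unit")
  v_res <- vc$vcov[vc$grp == "Residual"][1]
  v_fix <- var(fe[["age"]] * df$age)
  # LRT by full ML against the no-age null
  chi2 <- NA_real_
  if (lrt) {
    ml1 <- suppressMessages(lme4::lmer(form, data = df, REML = FALSE))
    ml0 <- suppressMessages(lme4::lmer(value ~ 1 + (1 | patient) + (1 | eye_unit),
                                       data = df, REML = FALSE))
    chi2 <- max(0, 2 * (as.numeric(logLik(ml1)) - as.numeric(logLik(ml0))))
  }
  structure(
    list(slope = unname(fe[["age"]]),
         slope_ci = unname(fe[["age"]] + c(-1, 1) * z * se),
         slope_se = unname(se), intercept = unname(fe[["(Intercept)"]]),
         vc = c(patient = v_pat, eye = v_eye, residual = v_res),
         chi2 = chi2, p = pf_chisq(chi2, 1),
         r2_marginal = v_fix / (v_fix + v_pat + v_eye + v_res),
         n_obs = nrow(df), n_eyes = length(unique(interaction(df$patient, df$eye))),
         n_patients = length(unique(df$patient)),
         crossed = crossed, conf = conf, model = fit),
    class = "lmm_fit"
  )
}

pf_chisq <- function(q, df) stats::pchisq(q, df, lower.tail = FALSE)

prepare_records <- function(records, metric = NULL) {
  df <- as.data.frame(records)
  if (!is.null(metric)) {
    if (!"metric" %in% names(df)) stop("records has no 'metric' column", call. = FALSE)
    df <- df[df$metric == metric, , drop = FALSE]
  }
  need <- c("value", "age", "patient")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("records missing columns: ", paste(miss, collapse = ", "),
                         call. = FALSE)
  if (!"eye" %in% names(df)) df$eye <- "right"
  df <- df[is.finite(df$value) & is.finite(df$age), , drop = FALSE]
  df
}

#' @export
print.lmm_fit <- function(x, ...) {
  cat(sprintf(
    "<lmm_fit> slope %.4g /y (%.0f%% CI %.4g to %.4g) | chi2(1) = %.1f, p = %.3g | R2m = %.3f\n",
    x$slope, 100 * x$conf, x$slope_ci[1], x$slope_ci[2], x$chi2, x$p, x$r2_marginal))
  cat(sprintf("  %d obs, %d eyes, %d patients | VC: patient %.3g, eye %.3g, residual %.3g\n",
              x$n_obs, x$n_eyes, x$n_patients, x$vc[1], x$vc[2], x$vc[3]))
  invisible(x)
}

#' Piecewise-linear (hinge) fit with profiled breakpoint search
#'
#' Fits the continuous two-segment model
#' `y = a + b0 * min(age - psi, 0) + b1 * max(age - psi, 0)` to pooled
#' longitudinal data. The breakpoint `psi` is profiled over a grid
#' (default step 0.1 years) between the second and second-to-last distinct
#' ages, minimizing the residual sum of squares, then refined by local
#' quadratic interpolation of the RSS profile. The 95% CI comes from a
#' case-resampling bootstrap over patients (so fellow eyes and repeat
#' visits resample together), seeded by the caller's RNG stream, as the
#' normal-approximation interval `psi_hat +/- z * sd(bootstrap psi)` —
#' better calibrated than percentile quantiles for this grid-discretized
#' estimator.
#'
#' @param records data.frame with `value`, `age`, `patient` (and
#'   optionally `metric`).
#' @param metric Optional metric name to filter on.
#' @param grid_step Breakpoint grid step, years.
#' @param n_boot Bootstrap replicates for the CI (0 skips the CI).
#' @param conf Confidence level.
#' @return Object of class `hinge_fit`: `psi`, `psi_ci`, `pre_slope`,
#'   `post_slope`, `intercept` (value at `psi`), `rss`, `rss_line`
#'   (single-line fit), and flags `boundary` (RSS minimum at the grid
#'   edge) and `indeterminate` (data collinear: hinge no better than a
#'   single line).
#' @export
fit_hinge <- function(records, metric = NULL, grid_step = 0.1, n_boot = 1000,
                      conf = 0.95) {
  df <- prepare_records(records, metric)
  ages <- sort(unique(df$age))
  if (length(ages) < 4) stop("need at least 4 distinct ages to fit a hinge", call. = FALSE)
  core <- hinge_profile(df$age, df$value, ages, grid_step)
  line <- lm.fit(cbind(1, df$age), df$value)
  rss_line <- sum(line$residuals^2)
  indeterminate <- core$rss >= rss_line - max(1e-10 * rss_line, 1e-12)
  psi_ci <- c(NA_real_, NA_real_)
  if (n_boot > 0) {
    pats <- unique(df$patient)
    by_pat <- split(seq_len(nrow(df)), df$patient)
    boot_psi <- vapply(seq_len(n_boot), function(b) {
      take <- sample(length(pats), replace = TRUE)
      idx <- unlist(by_pat[take], use.names = FALSE)
      a <- df$age[idx]; v <- df$value[idx]
      ua <- sort(unique(a))
      if (length(ua) < 4) return(NA_real_)
      hinge_profile(a, v, ua, grid_step)$psi
    }, numeric(1))
    z <- qnorm(1 - (1 - conf) / 2)
    psi_ci <- core$psi + c(-1, 1) * z * sd(boot_psi, na.rm = TRUE)
  }
  structure(
    c(core, list(psi_ci = psi_ci, rss_line = rss_line,
                 indeterminate = indeterminate, n_boot = n_boot, conf = conf,
                 n_obs = nrow(df), n_patients = length(unique(df$patient)))),
    class = "hinge_fit"
  )
}

# Closed-form least squares for the hinge basis [1, min(a-psi,0),
# max(a-psi,0)] via normal equations. The basis depends on age only, so
# observations are first collapsed to per-unique-age counts and y-sums;
# the two slope columns are entrywise-orthogonal (one of them is 0 at
# every observation), keeping the 3x3 system cheap.
hinge_ls <- function(ua, cnt, sy_a, psi, sy, syy, n) {
  d <- ua - psi
  x1 <- pmin(d, 0); x2 <- pmax(d, 0)
  s1 <- sum(cnt * x1); s2 <- sum(cnt * x2)
  s11 <- sum(cnt * x1 * x1); s22 <- sum(cnt * x2 * x2)
  x1y <- sum(x1 * sy_a); x2y <- sum(x2 * sy_a)
  # explicit inverse of [[n,s1,s2],[s1,s11,0],[s2,0,s22]] (Cramer)
  det <- n * s11 * s22 - s1 * s1 * s22 - s2 * s2 * s11
  scale_ref <- max(abs(n * s11 * s22), abs(s1 * s1 * s22), abs(s2 * s2 * s11), 1)
  if (!is.finite(det) || abs(det) < 1e-12 * scale_ref) {
    return(list(rss = Inf, coef = rep(NA_real_, 3)))
  }
  b0 <- (s11 * s22 * sy - s1 * s22 * x1y - s2 * s11 * x2y) / det
  b1 <- (-s1 * s22 * sy + (n * s22 - s2 * s2) * x1y + s1 * s2 * x2y) / det
  b2 <- (-s2 * s11 * sy + s1 * s2 * x1y + (n * s11 - s1 * s1) * x2y) / det
  rss <- max(syy - (b0 * sy + b1 * x1y + b2 * x2y), 0)
  list(rss = rss, coef = c(b0, b1, b2))
}

# Profiled grid search for the hinge breakpoint; returns psi, slopes,
# intercept at psi, rss, boundary flag.
hinge_profile <- function(age, value, distinct_ages, grid_step) {
  lo <- distinct_ages[2]; hi <- distinct_ages[length(distinct_ages) - 1]
  grid <- if (hi > lo) seq(lo, hi, by = grid_step) else lo
  sy <- sum(value); syy <- sum(value * value)
  n <- length(age)
  f_age <- match(age, distinct_ages)
  cnt <- tabulate(f_age, length(distinct_ages))
  sy_a <- as.numeric(rowsum(value, f_age, reorder = TRUE))
  ua <- distinct_ages[cnt > 0]
  sy_a <- sy_a[seq_along(ua)]  # rowsum drops empty groups
  cnt <- cnt[cnt > 0]
  rss <- vapply(grid, function(psi) hinge_ls(ua, cnt, sy_a, psi, sy, syy, n)$rss,
                numeric(1))
  i <- which.min(rss)
  psi <- grid[i]
  boundary <- i == 1L || i == length(grid)
  if (!boundary && length(grid) >= 3) {
    # local quadratic refinement on the RSS profile
    r0 <- rss[i - 1]; r1 <- rss[i]; r2 <- rss[i + 1]
    denom <- r0 - 2 * r1 + r2
    if (is.finite(denom) && denom > 0) {
      delta <- 0.5 * (r0 - r2) / denom
      if (abs(delta) <= 1) psi <- psi + delta * grid_step
    }
  }
  f <- hinge_ls(ua, cnt, sy_a, psi, sy, syy, n)
  list(psi = psi, pre_slope = unname(f$coef[2]), post_slope = unname(f$coef[3]),
       intercept = unname(f$coef[1]), rss = f$rss, boundary = boundary)
}

#' @export
print.hinge_fit <- function(x, ...) {
  cat(sprintf("<hinge_fit> psi = %.2f y (CI %.2f to %.2f) | slopes %.4g -> %.4g | RSS %.4g\n",
              x$psi, x$psi_ci[1], x$psi_ci[2], x$pre_slope, x$post_slope, x$rss))
  if (x$boundary) cat("  note: RSS minimum at the grid boundary\n")
  if (x$indeterminate) cat("  note: no better than a single line (collinear data)\n")
  invisible(x)
}

#' Repeated-measures (within-subject) correlation
#'
#' Within-subject correlation of paired repeated observations via the
#' analysis-of-covariance decomposition: subject-specific intercepts and a
#' common slope (`y ~ subject + x`), with
#' `r = sign(slope) * sqrt(SS_x / (SS_x + SS_error))` on the
#' subject-adjusted sums of squares. Error df is
#' `N - n_subjects - 1`; the p-value is the ANCOVA F test of the common
#' slope and the CI uses the Fisher z transform with
#' `se = 1 / sqrt(df - 1)` (the convention of the established
#' repeated-measures correlation implementations). Subjects contributing a
#' single pair are dropped with a warning.
#'
#' @param x,y Numeric vectors of paired observations.
#' @param subject Subject identifier vector (e.g. patient ID).
#' @param conf Confidence level.
#' @return Object of class `rmcorr_fit`: `r`, `ci`, `df`, `p`,
#'   `n_subjects`, `n_pairs`.
#' @export
#' @examples
#' s <- rep(1:4, each = 4); x <- rnorm(16); y <- x + rnorm(16, 0, .3) + s
#' rm_correlation(x, y, s)
rm_correlation <- function(x, y, subject, conf = 0.95) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]; subject <- factor(subject[ok])
  counts <- table(subject)
  if (any(counts < 2)) {
    warning(sprintf("dropping %d subject(s) with a single pair", sum(counts < 2)))
    keep <- subject %in% names(counts)[counts >= 2]
    x <- x[keep]; y <- y[keep]; subject <- droplevels(subject[keep])
  }
  n <- length(x)
  k <- nlevels(subject)
  if (k < 2 || n - k - 1 < 1) stop("not enough subjects/pairs for rm correlation",
                                   call. = FALSE)
  fit <- lm(y ~ subject + x)
  tab <- anova(fit)
  ss_x <- tab["x", "Sum Sq"]
  ss_e <- tab["Residuals", "Sum Sq"]
  df_e <- tab["Residuals", "Df"]
  slope <- coef(fit)[["x"]]
  r <- sign(slope) * sqrt(ss_x / (ss_x + ss_e))
  p <- tab["x", "Pr(>F)"]
  z <- atanh(r)
  se <- 1 / sqrt(df_e - 1)
  zc <- qnorm(1 - (1 - conf) / 2)
  structure(list(r = r, ci = tanh(z + c(-1, 1) * zc * se), df = df_e, p = p,
                 n_subjects = k, n_pairs = n, conf = conf),
            class = "rmcorr_fit")
}

#' @export
print.rmcorr_fit <- function(x, ...) {
  cat(sprintf("<rmcorr_fit> r = %.3f (%.0f%% CI %.3f to %.3f) | df = %d | p = %.3g\n",
              x$r, 100 * x$conf, x$ci[1], x$ci[2], x$df, x$p))
  invisible(x)
}

#' Dynamic-range normalized progression rate
#'
#' Expresses a slope as a percentage of the metric's dynamic range per
#' year: `100 * |slope| / dynamic_range`. This puts metrics with different
#' units (mm of sqrt-area, µm of EZ width, LogMAR) on a common footing.
#'
#' @param slope Progression rate in metric units / year.
#' @param dynamic_range Positive dynamic range in the same units; see
#'   [default_dynamic_range()].
#' @return Percent per year.
#' @export
#' @examples
#' normalized_rate(0.53, default_dynamic_range("sqrtAA_14mm"))  # ~4.3 %/y
normalized_rate <- function(slope, dynamic_range) {
  if (!is.numeric(dynamic_range) || dynamic_range <= 0) {
    stop("dynamic_range must be positive", call. = FALSE)
  }
  100 * abs(slope) / dynamic_range
}

#' Default dynamic ranges per metric
#'
#' * `sqrtAA_6mm`, `sqrtAA_14mm`: the square root of the full circle area,
#'   `sqrt(pi * (d/2)^2)` mm — the ceiling of the sqrt-transformed area.
#' * `EZ_total`: the full lateral scan extent (default 6000 µm for a
#'   20-degree macular scan).
#' * `CRT`, `PR_RPE`: the cohort baseline median (pass via
#'   `baseline_median`).
#' * `BCVA_logMAR`: the usable LogMAR span (default 1.5).
#'
#' @param metric Metric name.
#' @param scan_extent_um Lateral scan extent for `EZ_total`.
#' @param baseline_median Cohort baseline median for the thickness metrics.
#' @param bcva_span Usable LogMAR span.
#' @return Dynamic range in metric units.
#' @export
default_dynamic_range <- function(metric, scan_extent_um = 6000,
                                  baseline_median = NULL, bcva_span = 1.5) {
  switch(metric,
    sqrtAA_6mm = sqrt(pi * 3^2),
    sqrtAA_14mm = sqrt(pi * 7^2),
    EZ_total = scan_extent_um,
    CRT = ,
    PR_RPE = {
      if (is.null(baseline_median)) {
        stop("thickness metrics need a cohort baseline_median", call. = FALSE)
      }
      baseline_median
    },
    BCVA_logMAR = bcva_span,
    stop("unknown metric: ", metric, call. = FALSE)
  )
}

#' Exclude end-stage BCVA records from progression inputs
#'
#' Qualitative codes of counting fingers or worse mark end-stage disease
#' with limited utility as a trial outcome; they are removed from
#' progression modelling inputs (but should be retained in descriptive
#' tables upstream).
#'
#' @param records data.frame with a logical `end_stage` column (see
#'   [bcva_to_logmar()]).
#' @return The records with end-stage rows removed; warns when nothing is
#'   left.
#' @export
filter_endstage_bcva <- function(records) {
  stopifnot("end_stage" %in% names(records))
  out <- records[!records$end_stage, , drop = FALSE]
  if (nrow(out) == 0 && nrow(records) > 0) {
    warning("all records are end-stage; progression input is empty")
  }
  out
}

#' Bonferroni family-wise adjustment
#'
#' `min(1, p * family_size)` per p-value.
#'
#' @param p_values Numeric vector of raw p-values in `[0, 1]`.
#' @param family_size Number of tests in the family (defaults to
#'   `length(p_values)`).
#' @return Adjusted p-values.
#' @export
bonferroni_adjust <- function(p_values, family_size = length(p_values)) {
  if (any(!is.finite(p_values)) || any(p_values < 0 | p_values > 1)) {
    stop("p-values must lie in [0, 1]", call. = FALSE)
  }
  stopifnot(family_size >= 1)
  stats::p.adjust(p_values, method = "bonferroni", n = max(family_size, length(p_values)))
}
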