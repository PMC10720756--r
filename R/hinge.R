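#' Hinge (piecewise-linear) trajectory parameters
#'
#' The hinge model describes the dual-phase age course seen in LORD metrics:
#' stable (slope `pre_slope`, typically 0) until the inflection age
#' `breakpoint_age`, then a different linear slope `post_slope`. Variance
#' components generate patient- and eye-level random intercepts and visit
#' noise.
#'
#' @param breakpoint_age Inflection age psi, years.
#' @param pre_slope Slope before psi (metric units / year).
#' @param post_slope Slope after psi (metric units / year).
#' @param intercept_at_breakpoint Metric value at `age == breakpoint_age`
#'   (before random effects).
#' @param patient_intercept_sd,eye_intercept_sd,residual_sd Standard
#'   deviations (>= 0) of the patient intercept, eye-within-patient
#'   intercept, and residual visit noise, in metric units.
#' @return An object of class `hinge_params`.
#' @export
#' @examples
#' hp <- hinge_params(53.9, 0, 0.53, 0, patient_intercept_sd = 0.5,
#'                    eye_intercept_sd = 0.2, residual_sd = 0.15)
#' hinge_value(hp, c(50, 53.9, 63.9))
hinge_params <- function(breakpoint_age, pre_slope, post_slope,
                         intercept_at_breakpoint = 0,
                         patient_intercept_sd = 0, eye_intercept_sd = 0,
                         residual_sd = 0) {
  sds <- c(patient_intercept_sd, eye_intercept_sd, residual_sd)
  if (any(!is.finite(sds)) || any(sds < 0)) {
    stop("standard deviations must be finite and >= 0", call. = FALSE)
  }
  stopifnot(is.finite(breakpoint_age), is.finite(pre_slope), is.finite(post_slope),
            is.finite(intercept_at_breakpoint))
  structure(
    list(breakpoint_age = breakpoint_age, pre_slope = pre_slope,
         post_slope = post_slope,
         intercept_at_breakpoint = intercept_at_breakpoint,
         patient_intercept_sd = patient_intercept_sd,
         eye_intercept_sd = eye_intercept_sd, residual_sd = residual_sd),
    class = "hinge_params"
  )
}

#' Deterministic hinge trajectory value
#'
#' `value(age) = intercept + pre_slope * min(age - psi, 0) +
#'  post_slope * max(age - psi, 0)`.
#'
#' @param params A [hinge_params()] object.
#' @param ages Numeric vector of ages in years.
#' @return Numeric vector of metric values (no random effects).
#' @export
hinge_value <- function(params, ages) {
  stopifnot(inherits(params, "hinge_params"))
  d <- ages - params$breakpoint_age
  params$intercept_at_breakpoint +
    params$pre_slope * pmin(d, 0) + params$post_slope * pmax(d, 0)
}

#' Simulate one eye's metric series along a hinge trajectory
#'
#' Adds a patient random intercept, an eye random intercept, and residual
#' visit noise to the deterministic hinge. Interocular correlation between
#' fellow eyes is induced by passing the same `shared` component (patient
#' intercept plus the shared fraction of the visit-level noise) to both
#' eyes; see [shared_hinge_component()].
#'
#' Randomness is drawn from the current RNG stream; wrap calls in
#' [with_seed()] for reproducibility.
#'
#' @param params A [hinge_params()] object.
#' @param ages Sorted numeric vector of visit ages (years).
#' @param shared Optional list from [shared_hinge_component()] holding the
#'   patient intercept and shared noise for a fellow-eye pair. When `NULL`
#'   the patient intercept and all noise are drawn independently
#'   (`latent_share` is then ignored).
#' @param latent_share Fraction in `[0, 1]` of the residual variance shared
#'   between fellow eyes (only used with `shared`).
#' @return Numeric vector of simulated values, one per age, with the true
#'   random effects attached as attributes `u_patient` and `u_eye`.
#' @export
simulate_hinge_series <- function(params, ages, shared = NULL, latent_share = 0) {
  stopifnot(inherits(params, "hinge_params"))
  if (is.unsorted(ages, strictly = FALSE)) stop("ages must be sorted", call. = FALSE)
  m <- length(ages)
  base <- hinge_value(params, ages)
  if (is.null(shared)) {
    u_p <- rnorm(1, 0, params$patient_intercept_sd)
    eps <- rnorm(m, 0, params$residual_sd)
  } else {
    if (latent_share < 0 || latent_share > 1) {
      stop("latent_share must be in [0, 1]", call. = FALSE)
    }
    if (length(shared$eps_shared) != m) {
      stop("shared component length does not match ages", call. = FALSE)
    }
    u_p <- shared$u_patient
    eps <- sqrt(latent_share) * shared$eps_shared +
      sqrt(1 - latent_share) * rnorm(m, 0, params$residual_sd)
  }
  u_e <- rnorm(1, 0, params$eye_intercept_sd)
  out <- base + u_p + u_e + eps
  attr(out, "u_patient") <- u_p
  attr(out, "u_eye") <- u_e
  out
}

#' Draw the patient-level component shared by fellow eyes
#'
#' @param params A [hinge_params()] object.
#' @param ages Visit ages (years).
#' @return List with `u_patient` (scalar) and `eps_shared` (per-visit noise
#'   at the full residual sd; [simulate_hinge_series()] scales it by the
#'   shared fraction).
#' @export
shared_hinge_component <- function(params, ages) {
  stopifnot(inherits(params, "hinge_params"))
  list(u_patient = rnorm(1, 0, params$patient_intercept_sd),
       eps_shared = rnorm(length(ages), 0, params$residual_sd))
}

#' Shared-fraction calibration for a target within-subject correlation
#'
#' With fellow eyes sharing the deterministic trajectory, the patient
#' intercept, and a fraction `lambda` of the residual variance, the
#' within-subject (repeated-measures) correlation between fellow-eye series
#' observed at common ages is
#' `r = (V_h + lambda * s2) / (V_h + s2)`, where `V_h` is the
#' within-patient variance of the deterministic hinge across the visit ages
#' and `s2` the residual variance. This solves for `lambda` in closed form.
#'
#' @param params A [hinge_params()] object (uses `residual_sd`).
#' @param ages Common visit ages.
#' @param target_r Desired within-subject correlation in `(0, 1]`.
#' @return `lambda` in `[0, 1]`; warns and clamps when the trajectory alone
#'   already exceeds the target.
#' @export
latent_share_for_r <- function(params, ages, target_r) {
  stopifnot(inherits(params, "hinge_params"), target_r > 0, target_r <= 1)
  v_h <- stats::var(hinge_value(params, ages))
  s2 <- params$residual_sd^2
  if (s2 == 0) return(0)
  lambda <- (target_r * (v_h + s2) - v_h) / s2
  if (lambda < 0) {
    warning("trajectory variance alone exceeds target correlation; using lambda = 0")
    lambda <- 0
  }
  min(lambda, 1)
}
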