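# Shared builders for the test suite. Everything is generated in code; no
# binary fixtures.

# Minimal right-eye anatomy on a small raster.
tiny_anatomy <- function(fovea = c(150, 120), onh = c(270, 124), scale = 38) {
  eye_anatomy(fovea, onh, scale, "right")
}

# A blank exam with optional mask content.
tiny_exam <- function(h = 240, w = 340, anatomy = tiny_anatomy(),
                      eye = "right", age = 60, mask = NULL, image = NULL) {
  if (is.null(image)) image <- matrix(0.6, h, w)
  if (is.null(mask)) mask <- matrix(FALSE, h, w)
  faf_exam(image, mask, NULL, anatomy, "P01", eye, age)
}

# Simulate a two-eye longitudinal cohort from hinge parameters; returns
# the long data.frame used by the progression fitters.
sim_hinge_cohort <- function(params, ages, n_patients, latent_share = 0.5) {
  do.call(rbind, lapply(seq_len(n_patients), function(p) {
    sh <- shared_hinge_component(params, ages)
    do.call(rbind, lapply(c("right", "left"), function(e) {
      v <- simulate_hinge_series(params, ages, shared = sh,
                                 latent_share = latent_share)
      data.frame(value = as.numeric(v), age = ages,
                 patient = sprintf("P%02d", p), eye = e)
    }))
  }))
}

# Paired fellow-eye series calibrated in closed form to a target
# within-subject correlation: both eyes share the patient visit trajectory
# (hinge + patient intercept + visit noise); independent eye noise has
# variance V * (1 - r) / r where V is the within-subject variance of the
# shared series.
sim_paired_eyes <- function(params, ages, n_patients, target_r) {
  v_within <- var(hinge_value(params, ages)) + params$residual_sd^2
  sd_eye <- sqrt(v_within * (1 - target_r) / target_r)
  do.call(rbind, lapply(seq_len(n_patients), function(p) {
    s <- hinge_value(params, ages) +
      rnorm(1, 0, params$patient_intercept_sd) +
      rnorm(length(ages), 0, params$residual_sd)
    data.frame(patient = p,
               right = s + rnorm(length(ages), 0, sd_eye),
               left = s + rnorm(length(ages), 0, sd_eye))
  }))
}

# Small image-free cohort config for statistics-focused tests.
stats_config <- function(...) {
  cohort_config(render_images = FALSE, ...)
}
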