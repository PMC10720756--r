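---
title: "Quantifying LORD progression: models, maps, and the synthetic cohort"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying LORD progression: models, maps, and the synthetic cohort}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

Late-onset retinal degeneration (LORD) is an autosomal dominant dystrophy
caused by heterozygous *C1QTNF5* variants. Patients stay asymptomatic into
midlife, then lose the retinal pigment epithelium and outer retina over one
to two decades, with scalloped atrophy on fundus autofluorescence (FAF)
that typically appears in the temporal retina and spreads nasally. `lordprog`
implements the quantitative machinery for studying that natural history:
anatomically normalized FAF atrophy maps, scalar structural metrics, and
longitudinal models of their age course — together with a synthetic cohort
generator that provides ground truth for validating every stage.

```{r setup}
library(lordprog)
```

## The progression model

Every metric in the panel (square-root area of atrophy within fovea-centered
6 mm and 14 mm circles, ellipsoid-zone width, central retinal and
photoreceptor+RPE thickness, BCVA in LogMAR) follows a *hinge* trajectory:

$$y(a) = \alpha + \beta_0 \min(a - \psi, 0) + \beta_1 \max(a - \psi, 0)
        + u_{\text{patient}} + u_{\text{eye}} + \varepsilon$$

flat (or slowly drifting, slope $\beta_0$) until the inflection age $\psi$,
then linear with slope $\beta_1$. Three estimators target this model:

* **`fit_lmm()`** — the progression *rate*: a linear mixed model
  `value ~ age` with random intercepts for patient and eye-within-patient
  (REML via `lme4`), the standard structure when both eyes of each patient
  contribute repeated visits. The age effect is tested by a
  likelihood-ratio test (full-ML refits, 1 df) and the slope gets a Wald
  95% CI. The nested eye term reflects that the two eyes of one patient
  are the exchangeable sub-units; a crossed alternative (`crossed = TRUE`)
  treats laterality as its own grouping factor for sensitivity analyses.
  `r2_marginal` is the fixed-effects (marginal) share of total variance —
  one of several possible mixed-model R² conventions, stated explicitly
  because conventions differ.
* **`fit_hinge()`** — the inflection *age*: a continuous two-segment least
  squares fit with $\psi$ profiled on a grid (default 0.1 y) between the
  second and second-to-last distinct ages, refined by local quadratic
  interpolation of the RSS profile. Confidence intervals come from a
  case-resampling bootstrap over *patients*, so fellow eyes and repeat
  visits stay together; the bootstrap is explicitly seeded by the caller.
  With zero noise the breakpoint is recovered to within one grid step;
  single-line (collinear) data are flagged `indeterminate` rather than
  given a spurious breakpoint, and a grid-edge minimum is flagged
  `boundary`.
* **`rm_correlation()`** — interocular (and metric-metric) association:
  the repeated-measures correlation from the ANCOVA decomposition
  (subject-specific intercepts, common slope), with error df
  $N - k - 1$, the F test of the common slope, and a Fisher-z CI using
  $\mathrm{se} = 1/\sqrt{df - 1}$, matching the established
  repeated-measures-correlation implementations.

Slopes are comparable across metrics through `normalized_rate()`, percent
of dynamic range per year. The dynamic ranges are: the square root of the
full circle area for sqrt-AA ($\sqrt{\pi (d/2)^2}$, so 12.41 mm for the
14 mm circle), the lateral scan extent for EZ width (6000 µm for a
20-degree macular scan), the cohort baseline median for the thickness
metrics, and a usable LogMAR span (default 1.5) for BCVA. The thickness
and BCVA ranges are conventions, not physical ceilings, and are
configurable.

BCVA handling follows ophthalmic practice: qualitative end-stage entries
CF/HM/LP/NLP convert to 2.6/2.7/2.8/2.9 LogMAR (`bcva_to_logmar()`), and
records at counting-fingers or worse are excluded from progression fits
(`filter_endstage_bcva()`) while remaining available for descriptive
tables. Family-wise control across the metric panel uses
`bonferroni_adjust()`.

## From FAF image to atrophy map

The spatial pipeline normalizes each eye's anatomy so maps from different
eyes and visits share one frame:

1. **Right-eye format** — left eyes are mirrored about the vertical image
   midline (`flip_to_right_eye()`), so nasal is always +x. The mirror axis
   is the image midline rather than the fovea; downstream geometry is
   fovea-relative, so no re-centering is needed.
2. **Registration** — follow-up exams are aligned to baseline from at
   least 9 manually identified corresponding points via a least-squares
   projective transform (`estimate_projective()`): a direct linear
   transform with Hartley conditioning (centroid shift, $\sqrt2$ mean
   distance scaling), exact for noise-free points. Images resample
   bilinearly, masks nearest-neighbor (`apply_transform()`), and
   `reprojection_error()` provides the RMS quality check on the manual
   clicks. In the synthetic path, masks are segmented in the follow-up
   frame and warped to baseline; with real data either
   segment-after-warp or warp-after-segment order works, since the same
   transform is applied to whichever raster is segmented.
3. **Shear alignment** — a vertical shear of the fovea-and-nasal half
   (`shear_align()`, $y' = y - s(x - x_{fovea})$ with
   $s = \Delta y / \Delta x$ between fovea and ONH) levels the fovea and
   optic nerve head. The "nasal half" boundary is taken fovea-inclusive
   ($x \ge x_{fovea}$); the choice affects a single pixel column. Masks
   shift by whole pixels per column (nearest-neighbor inverse map), so
   binarity and per-column counts are preserved.
4. **Superpixel grid** — `build_grid()` picks the per-eye superpixel side
   $n = \mathrm{round}(|x_{ONH} - x_{fovea}| / 20)$ so that 20 superpixels
   separate fovea and disc, absorbing inter-individual fovea–disc
   distance variation. The grid anchors a superpixel *centered* on the
   fovea at index (0,0) — the natural reading of the published map
   convention, fixed here explicitly — and the ONH center then falls in
   index (20, 0). With integer $n$ the ONH lands within half a superpixel
   of its nominal center (the residual is below $n/2$ pixels and is
   accepted, matching the tolerance implied by per-eye superpixel
   rounding).
5. **Scoring** — `compute_atrophy_map()` assigns each superpixel the
   fraction of its pixels that are atrophic, after removing peripapillary
   atrophy, and binarizes at the inclusive threshold 0.5. Edge superpixels
   clipped by the frame are scored over in-frame pixels only and flagged,
   rather than padded with synthetic background.

Scalar area of atrophy (`area_of_atrophy()`) is measured in the
registered but *unsheared* frame — the shear exists only for the spatial
map — by counting mask pixels whose centers fall within the fovea-centered
circle (6 or 14 mm), excluding peripapillary pixels, and converting via
the pixel scale. The square root transform decouples growth-rate
estimates from baseline lesion size. A circle extending beyond the raster
triggers a warning and a `clipped` flag instead of silent truncation.

`stratify_and_prevalence()` pools binarized maps into 5-year age strata
(upper-inclusive intervals $(-\infty,55], (55,60], \ldots, (70,\infty)$ —
a convention fixed here since interval edges are ambiguous in prose) and
reports the percentage of examinations atrophic at each location,
censoring locations observed in fewer than 4 exams. Multiple exams per
eye may enter one stratum; this mirrors the pooled-examination design and
its acknowledged over-representation of frequently imaged patients, so no
per-patient weighting is applied by default.

## OCT and EZ width

`ez_width()` measures, on each side of the fovea, the distance to the
proximal edge of the first ellipsoid-zone absence run of lateral extent at
least `min_break_extent` (default twice the a-scan spacing). The
threshold operationalizes the distinction between clear EZ loss and mere
signal attenuation: a single-sample dropout never opens a break. A side
with no qualifying break is returned at the scan-edge distance with a
censoring flag — fully intact scans are thus retained as right-censored
widths rather than dropped or silently treated as complete, a choice that
keeps early-disease eyes in descriptive tables while letting analysts
exclude censored sides. Thickness metrics are strictly vertical
differences of boundary heights at the fovea: ILM to posterior RPE-Bruch's
for CRT, ELM to the same posterior border for PR+RPE; a missing boundary
yields `NA` with a warning, never a silent zero.

## The synthetic cohort

`generate_cohort()` emulates the statistical and spatial structure the
analysis assumes, with every generated quantity recorded in a ground-truth
ledger:

* **Trajectories.** Per-metric hinge parameters default to the published
  LORD panel (inflections 53.9/56.3/50.8/62.3/60/70.3 years; post-onset
  slopes 0.53 and 0.24 mm/y, −257, −4.7 and −3.8 µm/y, +0.05 LogMAR/y).
  Published natural-history reports do not include variance components,
  so the noise defaults are the package's own field-realistic choices and
  are stated as such: e.g. patient/eye/visit SDs of 0.5/0.2/0.15 mm for
  14-mm sqrt-AA, 300/120/150 µm for EZ width, 20/8/8 µm for CRT, and
  0.1/0.05/0.05 LogMAR for BCVA.
* **Interocular correlation** arises from fellow eyes sharing the
  deterministic trajectory, the patient intercept, and a configurable
  fraction λ of the visit-level noise. Because the within-subject
  correlation then equals $(V_h + \lambda\sigma^2)/(V_h + \sigma^2)$
  (with $V_h$ the within-patient variance of the trajectory),
  `latent_share_for_r()` solves for λ in closed form to hit a requested
  repeated-measures correlation.
* **Atrophy masks.** Scalloped lesions are modelled as a union of
  overlapping discs random-walking from a seed ~3.5 mm temporal of the
  fovea toward the nasal retina, followed by a confluence phase of larger
  lobes — no published generative model exists, and this construction
  reproduces the scalloped boundary and temporal-to-nasal growth order
  that the spatial analyses rely on. Internally a per-pixel *arrival
  index* over the disc family is thresholded at the exact pixel count for
  the target area, so realized areas match targets to one pixel and masks
  at increasing areas are strictly nested (atrophy never regresses).
  Targets beyond the disc union's reach raise a capacity error. The
  planted 14-mm sqrt-AA trajectory is squared to set each visit's total
  mask area; the ledger records both that target and the realized areas
  inside each circle, which fall short of the target once lesions grow
  past the circle or the frame.
* **Geometry.** Pixel scale and fovea-disc distance are sampled per eye
  from configurable ranges; the pixel distance is then snapped (by at
  most a few pixels, i.e. tens of micrometres) to the nearest value for
  which the integer-superpixel grid puts the ONH exactly at (20, 0), so
  the anatomical-normalization invariant is exact on synthetic eyes. A
  configurable fraction of eyes receives a peripapillary atrophy annulus
  to exercise the exclusion rule. Follow-up exams are misaligned by a
  planted random projective transform (translation, small rotation/scale,
  mild perspective, all scaled by `max_shift`) and ship with ≥9 exact
  control points, so registration can be validated against the planted
  homography.
* **OCT and clinic.** EZ traces realize the planted widths with the
  temporal half-width eroding before the nasal one (matching the
  temporal-first presentation); occasional single-sample dropouts test
  the attenuation rule. Boundary heights realize CRT and PR+RPE exactly.
  The clinical table renders BCVA at two decimals, switching to CF/HM/LP/
  NLP codes beyond 2.55 LogMAR.
* **Determinism.** All randomness flows from one master seed through
  per-eye substreams (stable hashing of patient/eye/context), so a
  configuration reproduces its cohort bit-for-bit regardless of
  evaluation order.

What the generator does *not* emulate — and what passing tests therefore
do not certify on real data: FAF texture (images are schematic background
plus hypo-autofluorescent lesion), segmentation ambiguity at lesion
borders, speckled or reticular autofluorescence preceding atrophy,
vendor-specific image geometry, floaters/vessel artifacts, and visit
schedules correlated with disease severity. Estimator behavior under
those conditions must be established against real, manually graded data.

## Numerical choices and degenerate inputs

* Homography estimation refuses fewer than `min_points` pairs (pipeline
  default 9, mathematical minimum 4) and rank-deficient (collinear)
  configurations; the DLT is solved by SVD after point conditioning.
* The hinge grid spans the second to second-to-last distinct ages, so
  both segments always have at least two support points; quadratic
  refinement is only applied at interior minima with positive curvature
  and is capped at one grid step.
* Mixed-model fits require at least 3 distinct ages and eyes with ≥2
  visits (the longitudinal inclusion rule); degenerate zero-variance data
  collapse to the OLS slope, at the cost of a singular-fit message.
* Fractions on clipped edge superpixels use in-frame pixel counts;
  conservation (Σ fraction × n² = atrophic pixel count) holds exactly
  over full superpixels.
* `with_seed()` snapshots and restores the caller's RNG state, so
  library calls never perturb user-level reproducibility.

## Problem sizes used in the validation suite

The bundled tests and the acceptance script run synthetic designs sized
like the published cohorts: 10–20 patients, both eyes, annual visits over
10–20 years spanning each breakpoint, bootstrap CIs at 149–199
replicates, and rasters of roughly 450×580 px at ~37 µm/px (with
1000×1152 px at 11.5 µm/px where fine-grid geometry is the point). These
sizes keep full runs in minutes while leaving all estimators
non-degenerate; all of them scale up by configuration.

## A worked example

```{r example, eval = FALSE}
cfg <- run_config(cohort = cohort_config(n_patients = 8, seed = 1),
                  out_dir = "lord_run")
res <- run_pipeline(cfg)
res$fits[, c("metric", "slope", "psi", "r_interocular", "p_bonferroni")]
```

The `fits.csv` artifact contains, per metric, the mixed-model rate with
CI, the LRT against no age effect (Bonferroni-adjusted across the panel),
the hinge inflection age with patient-bootstrap CI, and the interocular
repeated-measures correlation; `strata.csv` holds the age-stratified
spatial prevalence maps; `metrics.csv` the per-exam scalar metrics with
censoring and clipping flags.

## Known limitations

* The hinge CI is a normal-approximation bootstrap interval (bootstrap
  SE around the point estimate); in calibration simulations it holds
  coverage better than the percentile interval, whose quantiles are
  distorted by the grid discretization of the breakpoint, but
  profile-likelihood intervals are not implemented.
* The LRT for the age effect uses the χ²(1) reference; for very small
  cohorts a parametric bootstrap would be preferable.
* Registration assumes point correspondences are supplied (manual or
  planted); there is no automatic feature matching.
* Speckled/reticular autofluorescence quantification is out of scope; the
  atrophy definition is binary.
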