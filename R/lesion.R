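#' Lesion growth field for scalloped atrophy rendering
#'
#' The generative model for LORD-like scalloped atrophy is a union of
#' overlapping discs whose centers random-walk from a seed point temporal
#' to the fovea toward the nasal retina, with jittered, gradually enlarging
#' radii, followed by a confluence phase of larger discs re-centered on the
#' existing walk. Rather than rasterizing the union at one size, this
#' computes a per-pixel *arrival index* — the smallest
#' `disc index + normalized in-disc distance` over all discs covering the
#' pixel — so that thresholding the field at increasing levels yields a
#' strictly nested family of scalloped masks growing temporal to nasal.
#'
#' Randomness comes from the current RNG stream ([with_seed()]).
#'
#' @param anatomy An [eye_anatomy()] in right-eye format.
#' @param dim Raster dimensions `c(rows, cols)`.
#' @param n_walk,n_confluence Disc counts for the walk and confluence phases.
#' @param seed_offset_um Distance temporal of the fovea where the lesion
#'   originates (micrometres).
#' @param radius_range_um Disc radius ramp `c(start, end)` in micrometres.
#' @return Numeric matrix of arrival indices (`Inf` where no disc reaches).
#' @keywords internal
#' @export
lesion_arrival_field <- function(anatomy, dim, n_walk = 90, n_confluence = 60,
                                 seed_offset_um = 3500,
                                 radius_range_um = c(900, 3600)) {
  stopifnot(inherits(anatomy, "eye_anatomy"))
  h <- dim[1]; w <- dim[2]
  scale <- anatomy$pixel_scale
  arr <- matrix(Inf, h, w)
  n_total <- n_walk + n_confluence

  # temporal side = opposite the ONH (left of the fovea in right-eye
  # format, right of it for native left eyes)
  nasal_sign <- sign(fovea_disc_dx(anatomy))
  cx <- anatomy$fovea_xy[1] - nasal_sign * seed_offset_um / scale
  cy <- anatomy$fovea_xy[2]
  # drift from the temporal seed past the fovea toward the ONH
  span_px <- (seed_offset_um + 1.15 * abs(fovea_disc_dx(anatomy)) * scale) / scale
  step_px <- nasal_sign * span_px / n_walk
  centers <- matrix(NA_real_, n_total, 2)
  radii <- numeric(n_total)
  for (k in seq_len(n_walk)) {
    frac <- (k - 1) / max(n_total - 1, 1)
    r_um <- radius_range_um[1] + (radius_range_um[2] - radius_range_um[1]) * frac
    r <- r_um / scale * exp(rnorm(1, 0, 0.15))
    centers[k, ] <- c(cx, cy)
    radii[k] <- r
    cx <- cx + step_px * exp(rnorm(1, 0, 0.3))
    cy <- cy + rnorm(1, 0, 0.45 * r)
  }
  for (k in n_walk + seq_len(n_confluence)) {
    frac <- (k - 1) / max(n_total - 1, 1)
    r_um <- radius_range_um[1] + (radius_range_um[2] - radius_range_um[1]) * frac
    base_idx <- sample.int(k - 1, 1)
    centers[k, ] <- centers[base_idx, ] +
      rnorm(2, 0, c(0.6, 0.9) * radii[base_idx])
    radii[k] <- r_um / scale * exp(rnorm(1, 0, 0.2))
  }

  for (k in seq_len(n_total)) {
    ck <- centers[k, ]; r <- radii[k]
    y_lo <- max(0, ceiling(ck[2] - r)); y_hi <- min(h - 1, floor(ck[2] + r))
    if (y_lo > y_hi) next
    ys <- y_lo:y_hi
    half <- sqrt(pmax(r^2 - (ys - ck[2])^2, 0))
    x_lo <- pmax(0, ceiling(ck[1] - half))
    x_hi <- pmin(w - 1, floor(ck[1] + half))
    keep <- x_lo <= x_hi
    if (!any(keep)) next
    ys <- ys[keep]; x_lo <- x_lo[keep]; x_hi <- x_hi[keep]
    counts <- x_hi - x_lo + 1
    px <- sequence(counts) - 1 + rep(x_lo, counts)
    py <- rep(ys, counts)
    idx <- px * h + py + 1  # column-major linear index
    a <- k + sqrt((px - ck[1])^2 + (py - ck[2])^2) / r
    upd <- a < arr[idx]
    arr[idx[upd]] <- a[upd]
  }
  arr
}

#' Threshold an arrival field at an exact pixel count
#'
#' @param field Arrival field from [lesion_arrival_field()].
#' @param n_pixels Number of pixels to include (smallest arrival first;
#'   ties broken by linear index, making the selection deterministic).
#' @return Logical mask with exactly `n_pixels` `TRUE` entries.
#' @keywords internal
#' @export
mask_from_arrival <- function(field, n_pixels) {
  mask <- matrix(FALSE, nrow(field), ncol(field))
  if (n_pixels == 0) return(mask)
  finite <- which(is.finite(field))
  if (n_pixels > length(finite)) {
    stop("target area exceeds lesion-field capacity for this raster", call. = FALSE)
  }
  sel <- finite[order(field[finite], finite)[seq_len(n_pixels)]]
  mask[sel] <- TRUE
  mask
}

#' Render a scalloped atrophy mask of a given area
#'
#' Draws a lesion-growth field seeded temporal to the fovea (see
#' [lesion_arrival_field()]) and thresholds it at the pixel count matching
#' `target_area_mm2`, so the realized area differs from the target by at
#' most one pixel. For a fixed RNG seed, masks rendered at increasing
#' target areas are nested and expand nasally, reproducing the
#' temporal-onset, nasal-progression pattern of LORD atrophy.
#'
#' @inheritParams lesion_arrival_field
#' @param target_area_mm2 Target atrophy area in mm^2 (>= 0).
#' @param field Optional precomputed arrival field (reused across visits of
#'   one eye to guarantee nested growth).
#' @return Logical mask with attribute `area_mm2` (realized area).
#' @export
#' @examples
#' an <- eye_anatomy(c(190, 160), c(310, 160), pixel_scale = 40)
#' m <- with_seed(7, render_atrophy_mask(an, 20, dim = c(320, 380)))
#' attr(m, "area_mm2")
render_atrophy_mask <- function(anatomy, target_area_mm2, dim, field = NULL, ...) {
  stopifnot(inherits(anatomy, "eye_anatomy"))
  if (!is.numeric(target_area_mm2) || target_area_mm2 < 0) {
    stop("target_area_mm2 must be >= 0", call. = FALSE)
  }
  if (is.null(field)) field <- lesion_arrival_field(anatomy, dim, ...)
  px_area_mm2 <- (anatomy$pixel_scale / 1000)^2
  n <- round(target_area_mm2 / px_area_mm2)
  mask <- mask_from_arrival(field, n)
  attr(mask, "area_mm2") <- n * px_area_mm2
  mask
}

#' Render a peripapillary atrophy annulus at the ONH
#'
#' Exercises the peripapillary exclusion rule: a ring of atrophy around the
#' optic nerve head that must not count toward the area of atrophy.
#'
#' @inheritParams lesion_arrival_field
#' @param inner_um,outer_um Annulus radii in micrometres.
#' @return Logical mask.
#' @export
render_peripapillary_mask <- function(anatomy, dim, inner_um = 800, outer_um = 1150) {
  stopifnot(inherits(anatomy, "eye_anatomy"), outer_um > inner_um)
  h <- dim[1]; w <- dim[2]
  scale <- anatomy$pixel_scale
  xs <- rep(0:(w - 1), each = h) - anatomy$onh_xy[1]
  ys <- rep(0:(h - 1), times = w) - anatomy$onh_xy[2]
  d_um <- sqrt(xs^2 + ys^2) * scale
  matrix(d_um >= inner_um & d_um <= outer_um, h, w)
}
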