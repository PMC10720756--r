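#' Circle-restricted area of atrophy with square-root transform
#'
#' Counts atrophy pixels (peripapillary pixels excluded) whose centers lie
#' within a fovea-centered circle of the given diameter, and converts to
#' mm^2 via the pixel scale. Measurements are taken in the registered but
#' *unsheared* frame — the shear exists only for the superpixel map. The
#' square root of the area is returned alongside, decoupling growth-rate
#' estimates from baseline lesion size. The 6 mm circle matches the ETDRS
#' central subfield; the 14 mm circle captures most of a 55-degree field.
#'
#' @param mask Logical atrophy mask.
#' @param peripapillary_mask Logical exclusion mask or `NULL`.
#' @param anatomy An [eye_anatomy()] (fovea and pixel scale).
#' @param diameter_mm Circle diameter in mm (6 or 14 in the standard
#'   pipeline; any positive value accepted).
#' @return List with `area_mm2`, `sqrt_area_mm`, and `clipped` (`TRUE`,
#'   with a warning, when the circle extends beyond the raster and the
#'   area was computed on the available field).
#' @export
area_of_atrophy <- function(mask, peripapillary_mask = NULL, anatomy,
                            diameter_mm) {
  stopifnot(inherits(anatomy, "eye_anatomy"), diameter_mm > 0)
  h <- nrow(mask); w <- ncol(mask)
  if (is.null(peripapillary_mask)) peripapillary_mask <- matrix(FALSE, h, w)
  scale <- anatomy$pixel_scale
  r_px <- diameter_mm * 1000 / 2 / scale
  fx <- anatomy$fovea_xy[1]; fy <- anatomy$fovea_xy[2]
  clipped <- fx - r_px < 0 || fx + r_px > w - 1 || fy - r_px < 0 || fy + r_px > h - 1
  if (clipped) {
    warning(sprintf("%g mm circle extends beyond the raster; area computed on available field",
                    diameter_mm), call. = FALSE)
  }
  xs <- rep(0:(w - 1), each = h) - fx
  ys <- rep(0:(h - 1), times = w) - fy
  inside <- (xs^2 + ys^2) <= r_px^2
  cnt <- sum(as.vector(mask & !peripapillary_mask) & inside)
  area <- cnt * (scale / 1000)^2
  list(area_mm2 = area, sqrt_area_mm = sqrt(area), clipped = clipped)
}

#' OCT foveal B-scan derivatives
#'
#' Holds the manually derived quantities from the horizontal foveal
#' B-scan: the ellipsoid-zone (EZ) integrity trace over the lateral axis
#' (negative = temporal, positive = nasal, micrometres from the fovea) and
#' the layer-boundary heights at the fovea used for vertical thickness.
#'
#' @param lateral_um Strictly increasing lateral positions (µm); must
#'   sample the fovea (a position within half a spacing of 0).
#' @param ez_intact Logical vector, EZ present at each lateral position.
#' @param boundaries_um Named numeric: heights (µm, increasing downward)
#'   for `ILM`, `ELM`, `RPE_post` at the fovea; `NA` when a boundary could
#'   not be identified.
#' @param spacing_um A-scan spacing (µm); default inferred from
#'   `lateral_um`.
#' @return Object of class `oct_fovea_scan`.
#' @export
oct_fovea_scan <- function(lateral_um, ez_intact,
                           boundaries_um = c(ILM = NA_real_, ELM = NA_real_,
                                             RPE_post = NA_real_),
                           spacing_um = NULL) {
  if (length(lateral_um) != length(ez_intact)) {
    stop("lateral_um and ez_intact lengths differ", call. = FALSE)
  }
  if (is.unsorted(lateral_um, strictly = TRUE)) {
    stop("lateral_um must be strictly increasing", call. = FALSE)
  }
  if (is.null(spacing_um)) spacing_um <- median(diff(lateral_um))
  if (min(abs(lateral_um)) > spacing_um / 2) {
    stop("fovea (lateral position 0) is not sampled", call. = FALSE)
  }
  b <- c(ILM = NA_real_, ELM = NA_real_, RPE_post = NA_real_)
  b[names(boundaries_um)] <- boundaries_um
  structure(list(lateral_um = as.numeric(lateral_um),
                 ez_intact = as.logical(ez_intact),
                 boundaries_um = b, spacing_um = spacing_um),
            class = "oct_fovea_scan")
}

#' Ellipsoid-zone width: temporal, nasal, and total
#'
#' On each side of the fovea, the width runs from the fovea to the
#' proximal edge of the first EZ absence run of lateral extent at least
#' `min_break_extent` — short single-sample dropouts (signal attenuation
#' rather than clear EZ loss) do not qualify. A side with no qualifying
#' break within the scan returns the distance to the scan edge with its
#' censoring flag set. Total = temporal + nasal. If the EZ is absent at
#' the fovea itself all widths are 0.
#'
#' @param scan An [oct_fovea_scan()].
#' @param min_break_extent Minimum break extent in µm to count as clear EZ
#'   loss; default twice the a-scan spacing.
#' @return List with `temporal_um`, `nasal_um`, `total_um`,
#'   `censored_temporal`, `censored_nasal`, `fovea_absent`.
#' @export
ez_width <- function(scan, min_break_extent = 2 * scan$spacing_um) {
  stopifnot(inherits(scan, "oct_fovea_scan"))
  i0 <- which.min(abs(scan$lateral_um))
  if (!scan$ez_intact[i0]) {
    return(list(temporal_um = 0, nasal_um = 0, total_um = 0,
                censored_temporal = FALSE, censored_nasal = FALSE,
                fovea_absent = TRUE))
  }
  side_width <- function(idx) {
    # idx: sample indices ordered from the fovea outward (fovea excluded)
    pos <- abs(scan$lateral_um[idx])
    absent <- !scan$ez_intact[idx]
    edge <- if (length(pos)) max(pos) else 0
    if (!any(absent)) return(list(w = edge, censored = TRUE))
    r <- rle(absent)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1
    run_extent <- r$lengths * scan$spacing_um
    qualifying <- which(r$values & run_extent >= min_break_extent)
    if (!length(qualifying)) return(list(w = edge, censored = TRUE))
    first <- qualifying[1]
    list(w = pos[starts[first]], censored = FALSE)
  }
  nasal <- side_width(which(scan$lateral_um > scan$lateral_um[i0]))
  temporal <- side_width(rev(which(scan$lateral_um < scan$lateral_um[i0])))
  list(temporal_um = temporal$w, nasal_um = nasal$w,
       total_um = temporal$w + nasal$w,
       censored_temporal = temporal$censored, censored_nasal = nasal$censored,
       fovea_absent = FALSE)
}

#' Vertical foveal thickness between retinal boundaries
#'
#' `CRT` (central retinal thickness) spans inner limiting membrane to the
#' posterior border of the RPE-Bruch's membrane; `PR_RPE` (photoreceptor +
#' RPE complex) spans the external limiting membrane to the same posterior
#' border. Strictly vertical distance at lateral position 0.
#'
#' @param scan An [oct_fovea_scan()].
#' @param kind `"CRT"` or `"PR_RPE"`.
#' @return Thickness in µm, or `NA_real_` (with a warning) when a required
#'   boundary is missing — never a silent zero.
#' @export
foveal_thickness <- function(scan, kind = c("CRT", "PR_RPE")) {
  kind <- match.arg(kind)
  stopifnot(inherits(scan, "oct_fovea_scan"))
  b <- scan$boundaries_um
  top <- if (kind == "CRT") b[["ILM"]] else b[["ELM"]]
  if (is.na(top) || is.na(b[["RPE_post"]])) {
    warning(sprintf("missing boundary for %s at the fovea", kind), call. = FALSE)
    return(NA_real_)
  }
  b[["RPE_post"]] - top
}

#' Convert best-corrected visual acuity entries to LogMAR
#'
#' Numeric LogMAR values pass through; the qualitative end-stage codes
#' counting fingers, hand movement, light perception, and no light
#' perception convert to 2.6, 2.7, 2.8, and 2.9 LogMAR respectively. The
#' `end_stage` flag marks rows converted from a qualitative code (all at
#' or beyond 2.6 LogMAR) — these are excluded from progression modelling
#' by [filter_endstage_bcva()].
#'
#' @param x Character or numeric vector: numeric LogMAR values (possibly
#'   as strings) or codes `"CF"`, `"HM"`, `"LP"`, `"NLP"`.
#' @return data.frame with columns `logmar` and `end_stage`.
#' @export
#' @examples
#' bcva_to_logmar(c("0.30", "CF", "NLP"))
bcva_to_logmar <- function(x) {
  codes <- c(CF = 2.6, HM = 2.7, LP = 2.8, NLP = 2.9)
  if (is.numeric(x)) {
    return(data.frame(logmar = as.numeric(x), end_stage = rep(FALSE, length(x))))
  }
  xs <- toupper(trimws(as.character(x)))
  is_code <- xs %in% names(codes)
  suppressWarnings(num <- as.numeric(xs))
  bad <- !is_code & is.na(num) & !is.na(xs)
  if (any(bad)) {
    stop("unrecognized BCVA entries: ", paste(unique(xs[bad]), collapse = ", "),
         call. = FALSE)
  }
  logmar <- ifelse(is_code, codes[xs], num)
  data.frame(logmar = unname(logmar), end_stage = is_code)
}
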