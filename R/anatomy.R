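#' Eye anatomy: landmark coordinates and pixel scale
#'
#' Anchors all image geometry: fovea and optic nerve head (ONH) pixel
#' coordinates, the lateral pixel scale, and laterality. Coordinates are
#' 0-based, pixel-center convention, `x` rightward and `y` downward; in
#' right-eye format the ONH is nasal of (at larger `x` than) the fovea.
#'
#' @param fovea_xy Numeric length-2, fovea `(x, y)` in px.
#' @param onh_xy Numeric length-2, ONH center `(x, y)` in px.
#' @param pixel_scale Lateral scale in micrometres per pixel (> 0).
#' @param laterality `"right"` or `"left"`.
#' @return An object of class `eye_anatomy`.
#' @export
#' @examples
#' eye_anatomy(c(400, 300), c(700, 330), pixel_scale = 11.5, laterality = "right")
eye_anatomy <- function(fovea_xy, onh_xy, pixel_scale, laterality = c("right", "left")) {
  laterality <- match.arg(laterality)
  fovea_xy <- as.numeric(fovea_xy)
  onh_xy <- as.numeric(onh_xy)
  if (length(fovea_xy) != 2L || length(onh_xy) != 2L || anyNA(c(fovea_xy, onh_xy))) {
    stop("fovea_xy and onh_xy must be finite length-2 numeric vectors", call. = FALSE)
  }
  if (!is.numeric(pixel_scale) || length(pixel_scale) != 1L || !is.finite(pixel_scale) ||
      pixel_scale <= 0) {
    stop("pixel_scale must be a single positive number (um/px)", call. = FALSE)
  }
  if (all(fovea_xy == onh_xy)) {
    stop("fovea and ONH coordinates must differ", call. = FALSE)
  }
  structure(
    list(fovea_xy = fovea_xy, onh_xy = onh_xy,
         pixel_scale = pixel_scale, laterality = laterality),
    class = "eye_anatomy"
  )
}

#' @export
print.eye_anatomy <- function(x, ...) {
  cat(sprintf(
    "<eye_anatomy> %s eye | fovea (%.1f, %.1f) px | ONH (%.1f, %.1f) px | %.2f um/px\n",
    x$laterality, x$fovea_xy[1], x$fovea_xy[2], x$onh_xy[1], x$onh_xy[2], x$pixel_scale
  ))
  invisible(x)
}

#' Fovea-to-ONH horizontal pixel distance (signed)
#' @param anatomy An `eye_anatomy`.
#' @return Signed `x_onh - x_fovea` in px; positive means ONH nasal in
#'   right-eye format.
#' @export
fovea_disc_dx <- function(anatomy) {
  stopifnot(inherits(anatomy, "eye_anatomy"))
  anatomy$onh_xy[1] - anatomy$fovea_xy[1]
}
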