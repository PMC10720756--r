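#' Construct and validate a FAF exam
#'
#' Bundles the grayscale FAF raster, the binary atrophy and peripapillary
#' masks, the eye anatomy, and the exam identity. All rasters must share
#' one shape; masks are logical matrices on the same pixel grid.
#'
#' @param image Numeric matrix, grayscale FAF raster (values in `[0, 1]`).
#' @param atrophy_mask Logical matrix, manual atrophy segmentation.
#' @param peripapillary_mask Logical matrix of peripapillary atrophy to be
#'   excluded from analysis, or `NULL` for none.
#' @param anatomy An [eye_anatomy()].
#' @param patient_id,eye Identity strings (`eye` is `"right"`/`"left"`).
#' @param age_years Age at exam, years.
#' @param field_of_view `"55"` (wide) or `"30"` (narrow) degree-class field.
#' @return An object of class `faf_exam`.
#' @export
faf_exam <- function(image, atrophy_mask, peripapillary_mask = NULL, anatomy,
                     patient_id, eye = c("right", "left"), age_years,
                     field_of_view = c("55", "30")) {
  eye <- match.arg(eye)
  field_of_view <- match.arg(field_of_view)
  stopifnot(inherits(anatomy, "eye_anatomy"))
  if (!is.matrix(image) || !is.numeric(image)) {
    stop("image must be a numeric matrix", call. = FALSE)
  }
  atrophy_mask <- as_mask(atrophy_mask)
  if (is.null(peripapillary_mask)) {
    peripapillary_mask <- matrix(FALSE, nrow(image), ncol(image))
  } else {
    peripapillary_mask <- as_mask(peripapillary_mask)
  }
  if (!identical(dim(image), dim(atrophy_mask)) ||
      !identical(dim(image), dim(peripapillary_mask))) {
    stop("image and mask shapes differ", call. = FALSE)
  }
  if (!is.numeric(age_years) || length(age_years) != 1L || !is.finite(age_years) ||
      age_years < 0) {
    stop("age_years must be a single non-negative number", call. = FALSE)
  }
  for (pt in list(anatomy$fovea_xy, anatomy$onh_xy)) {
    if (pt[1] < 0 || pt[1] > ncol(image) - 1 || pt[2] < 0 || pt[2] > nrow(image) - 1) {
      stop("anatomy landmark falls outside the raster", call. = FALSE)
    }
  }
  structure(
    list(image = image, atrophy_mask = atrophy_mask,
         peripapillary_mask = peripapillary_mask, anatomy = anatomy,
         patient_id = as.character(patient_id), eye = eye,
         age_years = age_years, field_of_view = field_of_view,
         original_laterality = anatomy$laterality),
    class = "faf_exam"
  )
}

as_mask <- function(m) {
  if (!is.matrix(m)) stop("mask must be a matrix", call. = FALSE)
  if (is.logical(m)) return(m)
  if (is.numeric(m)) {
    if (any(!(m %in% c(0, 1)))) stop("mask must be binary", call. = FALSE)
    return(m > 0.5)
  }
  stop("mask must be logical or 0/1 numeric", call. = FALSE)
}

#' @export
print.faf_exam <- function(x, ...) {
  cat(sprintf(
    "<faf_exam> patient %s, %s eye, age %.1f y | %dx%d px, %s deg field | atrophy px: %d\n",
    x$patient_id, x$eye, x$age_years, nrow(x$image), ncol(x$image),
    x$field_of_view, sum(x$atrophy_mask)
  ))
  invisible(x)
}

#' Read a FAF exam from rasters plus a JSON sidecar
#'
#' Expects single-channel PNG or TIFF rasters for the image and masks, and
#' a JSON sidecar with keys `patient_id`, `eye`, `age_years`,
#' `pixel_scale_um_per_px`, `fovea_xy`, `onh_xy`, `laterality` (and
#' optionally `field_of_view`). Shape or metadata mismatches are rejected
#' with typed errors.
#'
#' @param image_path,atrophy_path Raster file paths (PNG or TIFF).
#' @param peripapillary_path Optional raster path, `NULL` for no
#'   peripapillary mask.
#' @param sidecar_path Path to the JSON sidecar.
#' @return A [faf_exam()].
#' @seealso [write_exam()]
#' @export
load_exam <- function(image_path, atrophy_path, peripapillary_path = NULL,
                      sidecar_path) {
  meta <- jsonlite::read_json(sidecar_path, simplifyVector = TRUE)
  required <- c("patient_id", "eye", "age_years", "pixel_scale_um_per_px",
                "fovea_xy", "onh_xy", "laterality")
  missing <- setdiff(required, names(meta))
  if (length(missing)) {
    stop("sidecar is missing keys: ", paste(missing, collapse = ", "), call. = FALSE)
  }
  if (meta$pixel_scale_um_per_px <= 0) {
    stop("sidecar pixel scale must be positive", call. = FALSE)
  }
  img <- read_raster(image_path)
  atr <- read_raster(atrophy_path) > 0.5
  ppa <- if (is.null(peripapillary_path)) NULL else read_raster(peripapillary_path) > 0.5
  anatomy <- eye_anatomy(
    fovea_xy = as.numeric(meta$fovea_xy), onh_xy = as.numeric(meta$onh_xy),
    pixel_scale = meta$pixel_scale_um_per_px, laterality = meta$laterality
  )
  faf_exam(
    image = img, atrophy_mask = atr, peripapillary_mask = ppa,
    anatomy = anatomy, patient_id = meta$patient_id, eye = meta$eye,
    age_years = meta$age_years,
    field_of_view = if (is.null(meta$field_of_view)) "55" else as.character(meta$field_of_view)
  )
}

#' Write a FAF exam as rasters plus a JSON sidecar
#'
#' @param exam A [faf_exam()].
#' @param dir Output directory (created if needed).
#' @param stem File-name stem; writes `<stem>_image.png`,
#'   `<stem>_atrophy.png`, `<stem>_peripapillary.png` (if non-empty) and
#'   `<stem>.json`.
#' @param format `"png"` or `"tiff"`.
#' @return Invisibly, the sidecar path.
#' @export
write_exam <- function(exam, dir, stem, format = c("png", "tiff")) {
  format <- match.arg(format)
  stopifnot(inherits(exam, "faf_exam"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ext <- if (format == "png") ".png" else ".tif"
  write_raster(exam$image, file.path(dir, paste0(stem, "_image", ext)), format)
  write_raster(exam$atrophy_mask * 1, file.path(dir, paste0(stem, "_atrophy", ext)), format)
  if (any(exam$peripapillary_mask)) {
    write_raster(exam$peripapillary_mask * 1,
                 file.path(dir, paste0(stem, "_peripapillary", ext)), format)
  }
  sidecar <- file.path(dir, paste0(stem, ".json"))
  jsonlite::write_json(
    list(patient_id = exam$patient_id, eye = exam$eye,
         age_years = exam$age_years,
         pixel_scale_um_per_px = exam$anatomy$pixel_scale,
         fovea_xy = exam$anatomy$fovea_xy, onh_xy = exam$anatomy$onh_xy,
         laterality = exam$anatomy$laterality,
         field_of_view = exam$field_of_view),
    sidecar, auto_unbox = TRUE, digits = NA
  )
  invisible(sidecar)
}

read_raster <- function(path) {
  ext <- tolower(tools::file_ext(path))
  arr <- switch(ext,
    png = png::readPNG(path),
    tif = ,
    tiff = tiff::readTIFF(path),
    stop("unsupported raster format: ", ext, call. = FALSE)
  )
  if (length(dim(arr)) == 3L) arr <- arr[, , 1]  # collapse to single channel
  arr
}

write_raster <- function(mat, path, format) {
  mat <- pmin(pmax(mat, 0), 1)
  if (format == "png") png::writePNG(mat, path) else tiff::writeTIFF(mat, path)
}

#' Mirror an exam into right-eye format
#'
#' Left eyes are flipped about the vertical image midline (`x' = W - 1 - x`
#' for image, masks, fovea, and ONH); right eyes pass through unchanged.
#' The output anatomy is annotated as right-format with the original
#' laterality retained in `original_laterality`. The operation is an
#' involution on coordinates and preserves mask pixel counts.
#'
#' @param exam A [faf_exam()].
#' @return A [faf_exam()] in right-eye format.
#' @export
flip_to_right_eye <- function(exam) {
  stopifnot(inherits(exam, "faf_exam"))
  if (exam$anatomy$laterality == "right") return(exam)
  w <- ncol(exam$image)
  mirror <- function(m) m[, w:1, drop = FALSE]
  anatomy <- exam$anatomy
  anatomy$fovea_xy[1] <- w - 1 - anatomy$fovea_xy[1]
  anatomy$onh_xy[1] <- w - 1 - anatomy$onh_xy[1]
  anatomy$laterality <- "right"
  out <- exam
  out$image <- mirror(exam$image)
  out$atrophy_mask <- mirror(exam$atrophy_mask)
  out$peripapillary_mask <- mirror(exam$peripapillary_mask)
  out$anatomy <- anatomy
  out$original_laterality <- exam$original_laterality
  out
}
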