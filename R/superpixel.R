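round_half_up <- function(x) floor(x + 0.5)

#' Vertically shear the nasal half-image to level fovea and ONH
#'
#' Computes the shear factor
#' `s = (y_onh - y_fovea) / (x_onh - x_fovea)` and, for every pixel with
#' `x >= x_fovea` (the fovea-and-nasal-ward half, boundary inclusive),
#' shifts the vertical coordinate by `y' = y - s * (x - x_fovea)`. The
#' temporal half is unchanged and horizontal coordinates are never
#' modified; after shearing, fovea and ONH share the same `y` to within
#' half a pixel. Masks are resampled nearest-neighbor on the inverse map
#' (whole columns shift by an integer), preserving binarity and, for
#' integer shifts, pixel counts.
#'
#' @param mask Logical (or numeric) raster in right-eye format.
#' @param anatomy An [eye_anatomy()] in right-eye format with the ONH nasal
#'   of the fovea.
#' @return List with `mask` (sheared raster), `shear` (factor `s`), and
#'   `anatomy` (landmarks in the sheared frame: ONH level with the fovea).
#' @export
#' @examples
#' an <- eye_anatomy(c(400, 300), c(700, 330), 11.5)
#' m <- matrix(FALSE, 600, 800); m[400, 500] <- TRUE
#' sh <- shear_align(m, an)
#' sh$shear  # 0.1
shear_align <- function(mask, anatomy) {
  stopifnot(inherits(anatomy, "eye_anatomy"))
  if (anatomy$laterality != "right") {
    stop("shear_align expects right-eye format (flip_to_right_eye first)", call. = FALSE)
  }
  dx <- fovea_disc_dx(anatomy)
  if (dx == 0) stop("degenerate anatomy: fovea and ONH share the same x", call. = FALSE)
  if (dx < 0) stop("ONH must be nasal (x > fovea) in right-eye format", call. = FALSE)
  s <- (anatomy$onh_xy[2] - anatomy$fovea_xy[2]) / dx
  h <- nrow(mask); w <- ncol(mask)
  out <- mask
  x_f <- anatomy$fovea_xy[1]
  cols <- which((0:(w - 1)) >= x_f)  # 1-based column numbers of sheared half
  for (cc in cols) {
    k <- round(s * ((cc - 1) - x_f))  # integer row shift for this column
    if (k == 0) next
    src <- (1:h) + k                  # inverse map: input row for each output row
    ok <- src >= 1 & src <= h
    col_new <- rep(if (is.logical(mask)) FALSE else 0, h)
    col_new[ok] <- mask[src[ok], cc]
    out[, cc] <- col_new
  }
  anat <- anatomy
  anat$onh_xy[2] <- anatomy$fovea_xy[2]
  list(mask = out, shear = s, anatomy = anat)
}

#' Build the fovea-anchored superpixel grid
#'
#' Chooses the per-eye superpixel side `n` (pixels) so that a fixed count
#' of 20 superpixels separates the fovea from the optic disc:
#' `n = round(|x_onh - x_fovea| / 20)` (half away from zero), `n >= 1`.
#' The grid is anchored with a superpixel *centered* on the fovea at index
#' `(0, 0)`; in the sheared frame the ONH center then falls in index
#' `(20, 0)`. The small per-eye variation of `n` absorbs anatomic
#' variability in fovea-disc distance so maps from different eyes share one
#' frame.
#'
#' @param anatomy An [eye_anatomy()] in the *sheared* right-eye frame
#'   (fovea and ONH level; see [shear_align()]).
#' @return Object of class `superpixel_grid`: list with `n`, `fovea_xy`,
#'   `onh_index`.
#' @export
build_grid <- function(anatomy) {
  stopifnot(inherits(anatomy, "eye_anatomy"))
  dx <- fovea_disc_dx(anatomy)
  if (dx <= 0) stop("ONH must be nasal of the fovea in right-eye format", call. = FALSE)
  if (dx < 20) stop("fovea-disc distance below 20 px: raster resolution too coarse",
                    call. = FALSE)
  n <- max(1, round_half_up(dx / 20))
  onh_index <- c(
    round_half_up(dx / n),
    round_half_up((anatomy$onh_xy[2] - anatomy$fovea_xy[2]) / n)
  )
  structure(list(n = as.integer(n), fovea_xy = anatomy$fovea_xy,
                 onh_index = as.integer(onh_index)),
            class = "superpixel_grid")
}

#' @export
print.superpixel_grid <- function(x, ...) {
  cat(sprintf("<superpixel_grid> n = %d px | fovea (0,0) at (%.1f, %.1f) px | ONH index (%d, %d)\n",
              x$n, x$fovea_xy[1], x$fovea_xy[2], x$onh_index[1], x$onh_index[2]))
  invisible(x)
}

#' Score per-superpixel atrophic fractions
#'
#' Each superpixel takes the proportion of its pixels that are atrophic
#' (excluding peripapillary-mask pixels) as value, and is classed atrophic
#' when that proportion reaches the threshold `theta` (inclusive;
#' default 0.5). Edge superpixels clipped by the image frame are scored
#' over their in-frame pixels only and flagged `full = FALSE`.
#'
#' @param mask Logical atrophy mask in the sheared frame.
#' @param peripapillary_mask Logical exclusion mask (same shape), or `NULL`.
#' @param grid A [build_grid()] result for the same frame.
#' @param theta Atrophic threshold on the fraction, inclusive.
#' @param exam_id,age_years Optional provenance carried as attributes.
#' @return Object of class `atrophy_map`: a data.frame with columns `gx`,
#'   `gy`, `fraction`, `atrophic`, `n_px`, `full`; attributes `n`, `theta`,
#'   `exam_id`, `age_years`.
#' @export
compute_atrophy_map <- function(mask, peripapillary_mask = NULL, grid,
                                theta = 0.5, exam_id = NA_character_,
                                age_years = NA_real_) {
  stopifnot(inherits(grid, "superpixel_grid"))
  h <- nrow(mask); w <- ncol(mask)
  if (grid$fovea_xy[1] < 0 || grid$fovea_xy[1] > w - 1 ||
      grid$fovea_xy[2] < 0 || grid$fovea_xy[2] > h - 1) {
    stop("grid/mask frame mismatch: fovea outside raster", call. = FALSE)
  }
  if (is.null(peripapillary_mask)) peripapillary_mask <- matrix(FALSE, h, w)
  if (!identical(dim(mask), dim(peripapillary_mask))) {
    stop("mask shapes differ", call. = FALSE)
  }
  eff <- mask & !peripapillary_mask
  n <- grid$n
  xs <- rep(0:(w - 1), each = h)
  ys <- rep(0:(h - 1), times = w)
  gx <- floor((xs - grid$fovea_xy[1]) / n + 0.5)
  gy <- floor((ys - grid$fovea_xy[2]) / n + 0.5)
  gx0 <- min(gx); gy0 <- min(gy)
  ngy <- max(gy) - gy0 + 1L
  id <- (gx - gx0) * ngy + (gy - gy0) + 1L
  nbins <- (max(gx) - gx0 + 1L) * ngy
  n_px <- tabulate(id, nbins)
  n_atr <- tabulate(id[as.vector(eff)], nbins)
  present <- which(n_px > 0)
  cell_gx <- (present - 1L) %/% ngy + gx0
  cell_gy <- (present - 1L) %% ngy + gy0
  fraction <- n_atr[present] / n_px[present]
  out <- data.frame(
    gx = cell_gx, gy = cell_gy, fraction = fraction,
    atrophic = fraction >= theta, n_px = n_px[present],
    full = n_px[present] == n * n
  )
  structure(out, class = c("atrophy_map", "data.frame"),
            n = n, theta = theta, exam_id = exam_id, age_years = age_years)
}

#' Write/read atrophy maps in long CSV form
#'
#' @param map An [compute_atrophy_map()] result.
#' @param path CSV path.
#' @return `path`, invisibly (reader returns the data.frame with
#'   attributes restored from columns).
#' @export
write_atrophy_map <- function(map, path) {
  df <- as.data.frame(map)
  df$exam_id <- attr(map, "exam_id")
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
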