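#' Control point pairs for projective registration
#'
#' Corresponding retinal detail coordinates identified on the baseline and
#' follow-up images (e.g. blood-vessel intersections). The pipeline default
#' requires at least 9 pairs, mirroring the manual selection protocol; 4
#' non-degenerate pairs are the mathematical minimum.
#'
#' @param x_base,y_base,x_follow,y_follow Numeric vectors of equal length,
#'   pixel coordinates.
#' @return An object of class `control_points` (a data.frame).
#' @export
control_points <- function(x_base, y_base, x_follow, y_follow) {
  n <- length(x_base)
  if (!all(lengths(list(y_base, x_follow, y_follow)) == n)) {
    stop("coordinate vectors must have equal length", call. = FALSE)
  }
  df <- data.frame(x_base = as.numeric(x_base), y_base = as.numeric(y_base),
                   x_follow = as.numeric(x_follow), y_follow = as.numeric(y_follow))
  if (anyNA(df) || any(!is.finite(as.matrix(df)))) {
    stop("control points must be finite", call. = FALSE)
  }
  if (anyDuplicated(df[, c("x_base", "y_base")]) ||
      anyDuplicated(df[, c("x_follow", "y_follow")])) {
    stop("duplicate control points", call. = FALSE)
  }
  class(df) <- c("control_points", "data.frame")
  df
}

#' Read/write control points as CSV
#' @param path CSV path with columns `x_base, y_base, x_follow, y_follow`.
#' @return A [control_points()] object.
#' @export
read_control_points <- function(path) {
  df <- utils::read.csv(path)
  control_points(df$x_base, df$y_base, df$x_follow, df$y_follow)
}

#' @rdname read_control_points
#' @param points A [control_points()] object.
#' @export
write_control_points <- function(points, path) {
  utils::write.csv(as.data.frame(points), path, row.names = FALSE)
  invisible(path)
}

#' Estimate the projective transform aligning follow-up to baseline
#'
#' Least-squares homography `H` (3x3, normalized so `H[3,3] = 1`) mapping
#' follow-up coordinates onto baseline coordinates, via the direct linear
#' transform with Hartley point conditioning (centroid shift and
#' sqrt(2)-mean-distance scaling of both point sets before solving; the
#' unconditioned system is numerically fragile). Exact for noise-free
#' correspondences.
#'
#' @param points A [control_points()] set.
#' @param min_points Minimum number of pairs required; the pipeline default
#'   of 9 reflects the manual selection protocol.
#' @return A 3x3 matrix of class `homography`.
#' @export
#' @examples
#' pts <- control_points(c(0, 100, 0, 100, 50), c(0, 0, 100, 100, 60),
#'                       c(0, 100, 0, 100, 50), c(0, 0, 100, 100, 60))
#' estimate_projective(pts, min_points = 4)  # identity
estimate_projective <- function(points, min_points = 9) {
  stopifnot(inherits(points, "control_points"))
  n <- nrow(points)
  if (n < max(min_points, 4L)) {
    stop(sprintf("insufficient control points: %d provided, %d required",
                 n, max(min_points, 4L)), call. = FALSE)
  }
  cond <- function(x, y) {
    cx <- mean(x); cy <- mean(y)
    d <- mean(sqrt((x - cx)^2 + (y - cy)^2))
    if (d < .Machine$double.eps) stop("degenerate control-point configuration", call. = FALSE)
    s <- sqrt(2) / d
    t <- matrix(c(s, 0, -s * cx, 0, s, -s * cy, 0, 0, 1), 3, 3, byrow = TRUE)
    list(T = t, x = s * (x - cx), y = s * (y - cy))
  }
  b <- cond(points$x_base, points$y_base)
  f <- cond(points$x_follow, points$y_follow)
  # DLT rows: for each pair, two equations in the 9 entries of H
  xf <- f$x; yf <- f$y; xb <- b$x; yb <- b$y
  a <- matrix(0, 2 * n, 9)
  a[seq(1, 2 * n, 2), ] <- cbind(xf, yf, 1, 0, 0, 0, -xb * xf, -xb * yf, -xb)
  a[seq(2, 2 * n, 2), ] <- cbind(0, 0, 0, xf, yf, 1, -yb * xf, -yb * yf, -yb)
  sv <- svd(a)
  if (sv$d[8] / sv$d[1] < 1e-10) {
    stop("rank-deficient (collinear or otherwise degenerate) control points",
         call. = FALSE)
  }
  h_hat <- matrix(sv$v[, 9], 3, 3, byrow = TRUE)
  h <- solve(b$T) %*% h_hat %*% f$T
  if (abs(h[3, 3]) < .Machine$double.eps) {
    stop("degenerate homography (vanishing normalization element)", call. = FALSE)
  }
  h <- h / h[3, 3]
  structure(h, class = c("homography", "matrix"))
}

#' @export
print.homography <- function(x, ...) {
  cat("<homography> follow-up -> baseline\n")
  print(unclass(x))
  invisible(x)
}

as_homography <- function(m) {
  m <- as.matrix(m)
  stopifnot(identical(dim(m), c(3L, 3L)), all(is.finite(m)))
  if (abs(det(m)) < .Machine$double.eps) stop("homography is singular", call. = FALSE)
  structure(m / m[3, 3], class = c("homography", "matrix"))
}

# Map 0-based pixel coordinates through a 3x3 projective matrix.
project_points <- function(m, x, y) {
  w <- m[3, 1] * x + m[3, 2] * y + m[3, 3]
  list(x = (m[1, 1] * x + m[1, 2] * y + m[1, 3]) / w,
       y = (m[2, 1] * x + m[2, 2] * y + m[2, 3]) / w)
}

# Inverse-warp a raster: out(x) = raster(M %*% x), 0-based pixel-center
# coordinates. kind "image" samples bilinearly, "mask" nearest-neighbor
# (preserving binarity); out-of-frame pixels are 0/FALSE.
warp_raster <- function(raster, m, kind = c("image", "mask")) {
  kind <- match.arg(kind)
  h <- nrow(raster); w <- ncol(raster)
  xs <- rep(0:(w - 1), each = h)
  ys <- rep(0:(h - 1), times = w)
  p <- project_points(m, xs, ys)
  if (kind == "mask") {
    sx <- round(p$x); sy <- round(p$y)
    ok <- sx >= 0 & sx <= w - 1 & sy >= 0 & sy <= h - 1
    out <- matrix(FALSE, h, w)
    # xs/ys enumerate output pixels in column-major order, so logical
    # subscripting by ok lines up with the linear layout of out
    out[ok] <- as.logical(raster[cbind(sy[ok] + 1, sx[ok] + 1)])
    if (!is.logical(raster)) out <- out * 1
    return(out)
  }
  val <- numeric(h * w)
  ok <- p$x >= 0 & p$x <= w - 1 & p$y >= 0 & p$y <= h - 1
  # clamp the lower cell corner so exact-boundary samples stay in frame
  x0 <- pmin(floor(p$x[ok]), w - 2); y0 <- pmin(floor(p$y[ok]), h - 2)
  fx <- p$x[ok] - x0; fy <- p$y[ok] - y0
  i00 <- cbind(y0 + 1, x0 + 1)
  i01 <- cbind(y0 + 1, x0 + 2)
  i10 <- cbind(y0 + 2, x0 + 1)
  i11 <- cbind(y0 + 2, x0 + 2)
  val[ok] <- raster[i00] * (1 - fx) * (1 - fy) +
    raster[i01] * fx * (1 - fy) +
    raster[i10] * (1 - fx) * fy +
    raster[i11] * fx * fy
  matrix(val, h, w)
}

#' Resample a raster onto the baseline grid under a homography
#'
#' Inverse-warps: each baseline pixel samples the follow-up raster at
#' `H^{-1} x`. Images are interpolated bilinearly; masks use
#' nearest-neighbor sampling and remain binary. Out-of-frame pixels become
#' 0 / `FALSE`.
#'
#' @param raster Numeric or logical matrix in follow-up frame.
#' @param H A [homography][estimate_projective()] mapping follow-up
#'   coordinates onto baseline.
#' @param kind `"image"` or `"mask"`.
#' @return Raster on the baseline grid.
#' @export
apply_transform <- function(raster, H, kind = c("image", "mask")) {
  kind <- match.arg(kind)
  H <- as_homography(H)
  warp_raster(raster, solve(H), kind)
}

#' Root-mean-square reprojection error of control points under a homography
#'
#' Quality control for the manual point selection: RMS distance in px
#' between `H`-mapped follow-up points and their baseline counterparts.
#'
#' @inheritParams apply_transform
#' @param points A [control_points()] set.
#' @return RMS error in pixels.
#' @export
reprojection_error <- function(points, H) {
  stopifnot(inherits(points, "control_points"))
  H <- as_homography(H)
  p <- project_points(H, points$x_follow, points$y_follow)
  sqrt(mean((p$x - points$x_base)^2 + (p$y - points$y_base)^2))
}

#' Misalign a follow-up exam with a planted projective transform
#'
#' Applies a random projective transform (translation, small rotation and
#' scale, mild perspective — all proportional to `max_shift`) to the exam's
#' image and masks, emulating acquisition misalignment of follow-up FAF
#' images, and emits `n_points` exact corresponding control-point pairs.
#' The planted homography maps the perturbed (follow-up) frame back onto
#' the original (baseline) frame, so [estimate_projective()] on the emitted
#' points recovers it exactly.
#'
#' Randomness comes from the current RNG stream ([with_seed()]).
#'
#' @param exam A [faf_exam()] in the baseline frame.
#' @param max_shift Maximum translation magnitude in px; 0 plants the
#'   identity.
#' @param n_points Number of control-point pairs to emit (>= 9 by default).
#' @return List with elements `exam` (misaligned copy), `points`
#'   ([control_points()]), and `homography` (planted, follow-up ->
#'   baseline).
#' @export
perturb_followup <- function(exam, max_shift = 12, n_points = 9) {
  stopifnot(inherits(exam, "faf_exam"), max_shift >= 0, n_points >= 4)
  w <- ncol(exam$image); h <- nrow(exam$image)
  tx <- runif(1, -1, 1) * max_shift
  ty <- runif(1, -1, 1) * max_shift
  th <- runif(1, -1, 1) * max_shift * 0.0015          # radians
  sc <- 1 + runif(1, -1, 1) * max_shift * 5e-4
  g <- runif(1, -1, 1) * max_shift / (4 * w^2)         # perspective terms
  k <- runif(1, -1, 1) * max_shift / (4 * h^2)
  rot <- matrix(c(cos(th), -sin(th), 0, sin(th), cos(th), 0, 0, 0, 1), 3, 3, byrow = TRUE)
  # rotate/scale about the image center so displacement stays ~max_shift
  cx <- (w - 1) / 2; cy <- (h - 1) / 2
  ctr <- matrix(c(1, 0, -cx, 0, 1, -cy, 0, 0, 1), 3, 3, byrow = TRUE)
  unctr <- matrix(c(1, 0, cx, 0, 1, cy, 0, 0, 1), 3, 3, byrow = TRUE)
  trans <- matrix(c(sc, 0, tx, 0, sc, ty, 0, 0, 1), 3, 3, byrow = TRUE)
  persp <- matrix(c(1, 0, 0, 0, 1, 0, g, k, 1), 3, 3, byrow = TRUE)
  h_f2b <- as_homography(unctr %*% trans %*% rot %*% persp %*% ctr)
  h_b2f <- solve(h_f2b)

  out <- exam
  # follow(x_f) = base(H_f2b x_f): inverse-warp the baseline content
  out$image <- warp_raster(exam$image, h_f2b, "image")
  out$atrophy_mask <- warp_raster(exam$atrophy_mask, h_f2b, "mask")
  out$peripapillary_mask <- warp_raster(exam$peripapillary_mask, h_f2b, "mask")
  fv <- project_points(h_b2f, exam$anatomy$fovea_xy[1], exam$anatomy$fovea_xy[2])
  oh <- project_points(h_b2f, exam$anatomy$onh_xy[1], exam$anatomy$onh_xy[2])
  out$anatomy$fovea_xy <- c(fv$x, fv$y)
  out$anatomy$onh_xy <- c(oh$x, oh$y)

  # non-collinear baseline grid spanning the central field, jittered
  side <- ceiling(sqrt(n_points))
  gx <- seq(0.2, 0.8, length.out = side) * (w - 1)
  gy <- seq(0.2, 0.8, length.out = side) * (h - 1)
  grid <- expand.grid(x = gx, y = gy)[seq_len(n_points), ]
  grid$x <- grid$x + runif(n_points, -0.02, 0.02) * w
  grid$y <- grid$y + runif(n_points, -0.02, 0.02) * h
  pf <- project_points(h_b2f, grid$x, grid$y)
  pts <- control_points(grid$x, grid$y, pf$x, pf$y)
  list(exam = out, points = pts, homography = h_f2b)
}
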