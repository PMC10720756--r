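# Planted homography fixture independently verified with an external
# projective-transform implementation (recovered to < 5e-13):
planted_H <- matrix(c(1.02, 0.03, 5.0,
                      -0.02, 0.98, -3.0,
                      1e-5, -2e-5, 1.0), 3, 3, byrow = TRUE)
follow_pts <- matrix(c(
  89.874466958945, 106.809942776108,
  483.144040017242, 115.219984562487,
  879.389420512975, 123.693663778791,
  77.211992749676, 510.030605877517,
  467.196898145847, 519.878709549137,
  860.108373499386, 529.80071650251,
  64.755523681341, 906.691292772303,
  451.510161419147, 917.929653989133,
  841.143343527619, 929.251660282867), ncol = 2, byrow = TRUE)
# base rows must pair with follow rows: expand.grid varies x fastest
base_ordered <- data.frame(x = rep(c(100, 500, 900), 3),
                           y = rep(c(100, 500, 900), each = 3))

test_that("estimate_projective recovers a planted homography exactly", {
  pts <- control_points(base_ordered$x, base_ordered$y,
                        follow_pts[, 1], follow_pts[, 2])
  H <- estimate_projective(pts)
  expect_lt(max(abs(H - planted_H)), 1e-8)
  expect_lt(reprojection_error(pts, H), 1e-8)
})

test_that("identical point pairs give the identity transform", {
  xs <- c(10, 200, 30, 180, 90, 140, 60, 120, 250)
  ys <- c(20, 40, 210, 190, 100, 30, 150, 240, 120)
  pts <- control_points(xs, ys, xs, ys)
  H <- estimate_projective(pts)
  expect_equal(unclass(H), diag(3), tolerance = 1e-10, ignore_attr = TRUE)
})

test_that("point-count and degeneracy guards reject bad input", {
  xs <- c(10, 200, 30, 180, 90, 140, 60, 120)
  ys <- c(20, 40, 210, 190, 100, 30, 150, 240)
  pts8 <- control_points(xs, ys, xs, ys)
  expect_error(estimate_projective(pts8), "insufficient")
  expect_s3_class(estimate_projective(pts8, min_points = 4), "homography")

  on_line <- control_points(1:9, 2 * (1:9) + 3, 1:9, 2 * (1:9) + 3)
  expect_error(estimate_projective(on_line), "degenerate|rank")
  expect_error(control_points(c(1, 1), c(2, 2), c(3, 4), c(5, 6)), "duplicate")
})

test_that("homography composition is consistent", {
  h1 <- matrix(c(1.01, 0.02, 4, -0.01, 0.99, -2, 2e-6, -1e-6, 1), 3, 3, byrow = TRUE)
  h2 <- matrix(c(0.98, -0.03, -6, 0.02, 1.02, 3, -2e-6, 3e-6, 1), 3, 3, byrow = TRUE)
  h12 <- h1 %*% h2
  h12 <- h12 / h12[3, 3]
  xf <- base_ordered$x; yf <- base_ordered$y
  w <- h12[3, 1] * xf + h12[3, 2] * yf + h12[3, 3]
  xb <- (h12[1, 1] * xf + h12[1, 2] * yf + h12[1, 3]) / w
  yb <- (h12[2, 1] * xf + h12[2, 2] * yf + h12[2, 3]) / w
  H <- estimate_projective(control_points(xb, yb, xf, yf))
  expect_lt(max(abs(H - h12)), 1e-8)
})

test_that("apply_transform warps images and keeps masks binary", {
  img <- matrix(runif(120 * 150), 120, 150)
  expect_equal(apply_transform(img, diag(3), "image"), img)

  mask <- matrix(FALSE, 120, 150); mask[40:70, 50:90] <- TRUE
  expect_identical(apply_transform(mask, diag(3), "mask"), mask)

  # integer translation preserves mask pixel count
  tr <- diag(3); tr[1, 3] <- 7; tr[2, 3] <- -5  # follow -> base shift
  shifted <- apply_transform(mask, tr, "mask")
  expect_type(shifted, "logical")
  expect_equal(sum(shifted), sum(mask))

  expect_error(apply_transform(mask, matrix(0, 3, 3), "mask"), "singular|finite")
})

test_that("warp then inverse-warp nearly recovers a smooth mask", {
  h <- 200; w <- 240
  xs <- rep(0:(w - 1), each = h); ys <- rep(0:(h - 1), times = w)
  disc <- matrix((xs - 120)^2 + (ys - 100)^2 <= 55^2, h, w)
  H <- matrix(c(1.005, 0.012, 6, -0.008, 0.996, -4, 1e-6, -2e-6, 1), 3, 3,
              byrow = TRUE)
  there <- apply_transform(disc, solve(H), "mask")   # into follow-up frame
  back <- apply_transform(there, H, "mask")          # and back to baseline
  jaccard <- sum(back & disc) / sum(back | disc)
  expect_gt(jaccard, 0.99)
})

test_that("reprojection error measures RMS point mismatch", {
  xs <- c(10, 200, 30, 180, 90, 140, 60, 120, 250)
  ys <- c(20, 40, 210, 190, 100, 30, 150, 240, 120)
  exact <- control_points(xs, ys, xs, ys)
  expect_equal(reprojection_error(exact, diag(3)), 0)

  # identity on points shifted by d gives RMS exactly d
  d <- 3.5
  shifted <- control_points(xs + d, ys, xs, ys)
  expect_equal(reprojection_error(shifted, diag(3)), d)

  # isotropic jitter of sd sigma on both coordinates gives RMS ~ sigma*sqrt(2)
  sigma <- 0.8
  n <- 4000
  px <- runif(n, 0, 500); py <- runif(n, 0, 500)
  jit <- with_seed(4, control_points(px + rnorm(n, 0, sigma),
                                     py + rnorm(n, 0, sigma), px, py))
  expect_equal(reprojection_error(jit, diag(3)), sigma * sqrt(2), tolerance = 0.05)
})
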