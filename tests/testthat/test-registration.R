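fm <- function(xl, yl, xr, yr) {
  structure(data.frame(xl = xl, yl = yl, xr = xr, yr = yr,
                       distance = 0),
            class = c("feature_match_set", "data.frame"))
}

test_that("epipolar filter keeps row-consistent, non-negative disparity pairs", {
  m <- fm(xl = c(100, 100, 100, 50), yl = c(50, 50, 50, 40),
          xr = c(90, 95, 120, 49), yr = c(50, 100, 50, 41))
  out <- filter_epipolar(m, 2)
  # pair 2 fails the row test (dy = 50), pair 3 has xl < xr
  expect_equal(nrow(out), 2L)
  expect_equal(out$xr, c(90, 49))
  # projected synthetic points on a forward-facing rectified rig always
  # have xl >= xr
  rig <- test_rig()
  f <- rig$cameras$left$f; cx <- rig$cameras$left$cx; cy <- rig$cameras$left$cy
  set.seed(2)
  P <- cbind(runif(40, -300, 300), runif(40, -150, 150), runif(40, 1100, 1600))
  xl <- f * P[, 1] / P[, 3] + cx
  xr <- f * (P[, 1] - 60) / P[, 3] + cx
  expect_true(all(xl >= xr))
})

test_that("triangulation implements the depth relations and excludes d <= 0", {
  m <- fm(xl = c(240, 100, 300), yl = c(60, 143.5, 80),
          xr = c(200, 100, 299), yr = c(60, 143.5, 80))
  intr <- list(f = 800, cx = 191.5, cy = 143.5, baseline = 60)
  wp <- triangulate_matches(m, intr)
  # B = 60, f = 800, d = 40 -> Z = 1200
  expect_equal(unname(wp[1, "Z"]), 1200)
  expect_equal(attr(wp, "n_excluded"), 1L)  # the zero-disparity pair
  expect_equal(attr(wp, "kept"), c(1L, 3L))
  # pair at the principal point has X = Y = 0
  m2 <- fm(xl = 191.5, yl = 143.5, xr = 151.5, yr = 143.5)
  wp2 <- triangulate_matches(m2, intr)
  expect_equal(unname(wp2[1, c("X", "Y")]), c(0, 0))
})

test_that("back-projection matches explicit matrix arithmetic", {
  K <- matrix(c(380, 0, 191.5, 0, 380, 143.5, 0, 0, 1), 3, 3, byrow = TRUE)
  # optical-axis point with identity pose lands on the principal point
  p <- backproject_to_thermal(cbind(0, 0, 1300), list(K = K, R = diag(3),
                                                      T = c(0, 0, 0)))
  expect_equal(unname(p[1, ]), c(191.5, 143.5))

  R <- canopy3d:::rotation_xyz(c(0.02, -0.03, 0.01))
  T <- c(25, -10, 3)
  P <- c(120, -80, 1400)
  q <- backproject_to_thermal(rbind(P), list(K = K, R = R, T = T))
  cam <- as.numeric(R %*% P + T)
  manual <- K %*% cam
  expect_equal(unname(q[1, ]), c(manual[1] / manual[3], manual[2] / manual[3]))
  # homogeneous scaling of the world point leaves the pixel unchanged
  # (projective invariance: scaling (X,Y,Z,1) by l rescales s)
  expect_equal(unname(attr(q, "scale_s")), cam[3])
  # point behind the camera is excluded, not an error
  q2 <- backproject_to_thermal(rbind(c(0, 0, -500), P),
                               list(K = K, R = diag(3), T = c(0, 0, 0)))
  expect_equal(attr(q2, "kept"), 2L)
})

test_that("RANSAC homography recovers exact and contaminated correspondences", {
  set.seed(11)
  H_true <- matrix(c(1.05, 0.03, 8, -0.02, 0.97, -5, 2e-4, -1e-4, 1),
                   3, 3, byrow = TRUE)
  src <- cbind(runif(8, 10, 370), runif(8, 10, 270))
  dst <- apply_homography(H_true, src)
  est <- estimate_homography_ransac(src, dst, 3, seed = 1)
  expect_lt(est$residual, 1e-6)
  expect_lt(max(abs(est$H - H_true)), 1e-6)

  # identity correspondences give the identity
  id <- estimate_homography_ransac(src, src, 3, seed = 1)
  expect_lt(max(abs(id$H - diag(3))), 1e-9)

  # 70% inliers + 30% uniform outliers, n = 100
  set.seed(4)
  src2 <- cbind(runif(100, 0, 380), runif(100, 0, 280))
  dst2 <- apply_homography(H_true, src2)
  out_idx <- 71:100
  dst2[out_idx, ] <- cbind(runif(30, 0, 380), runif(30, 0, 280))
  est2 <- estimate_homography_ransac(src2, dst2, 3, seed = 7)
  inl_err <- canopy3d:::reprojection_errors(H_true, src2[est2$inliers, ],
                                            apply_homography(est2$H, src2[est2$inliers, ]))
  expect_lte(mean(inl_err), 0.5)
  expect_error(estimate_homography_ransac(src[1:3, ], dst[1:3, ]), ">= 4")
  # reproducibility under the seed
  est3 <- estimate_homography_ransac(src2, dst2, 3, seed = 7)
  expect_identical(est2$H, est3$H)
})

test_that("SSIM matches the direct formula oracle and its bounds", {
  img <- textured_image(40, 40, seed = 2)
  expect_equal(ssim(img, img), 1.0, tolerance = 1e-12)
  neg <- 255 - img
  expect_lt(ssim(img, neg), 1)
  set.seed(3)
  a <- matrix(runif(64, 0, 255), 8, 8)
  b <- matrix(runif(64, 0, 255), 8, 8)
  expect_equal(ssim(a, b), oracle_ssim(a, b), tolerance = 1e-10)
  expect_error(ssim(a, matrix(0, 9, 8)), "differ")
})

test_that("thermal warping follows the homography with invalid marking", {
  set.seed(5)
  pc <- array(runif(40 * 50 * 3, 0, 255), c(40, 50, 3))
  temps <- matrix(round(runif(40 * 50, 20, 30), 1), 40, 50)
  fr <- thermal_frame(pc, temps)

  w_id <- warp_thermal(fr, diag(3))
  expect_equal(w_id$temperature, temps)
  expect_equal(w_id$pseudo_color, pc, tolerance = 1e-9)

  # integer translation: exact shift, vacated band invalid
  H_t <- diag(3); H_t[1, 3] <- 5
  w_t <- warp_thermal(fr, H_t)
  expect_true(all(is.na(w_t$temperature[, 1:5])))
  expect_equal(w_t$temperature[, 6:50], temps[, 1:45])

  # a labelled hot pixel lands at the H-mapped coordinate (nearest pixel)
  temps2 <- matrix(22, 40, 50); temps2[20, 25] <- 35
  fr2 <- thermal_frame(pc, temps2)
  H <- matrix(c(1.02, 0.01, 2.3, -0.01, 0.99, -1.7, 1e-5, 0, 1), 3, 3,
              byrow = TRUE)
  mapped <- apply_homography(H, cbind(24, 19))  # 0-based source pixel
  w2 <- warp_thermal(fr2, H)
  expect_equal(w2$temperature[round(mapped[2]) + 1, round(mapped[1]) + 1], 35)
  expect_error(warp_thermal(fr, matrix(0, 3, 3)), "singular")

  # warp H then H^-1 restores the doubly-valid region within interpolation
  # tolerance (smooth image: bilinear resampling error, not aliasing)
  smooth <- outer(1:40, 1:50, function(y, x)
    127 + 60 * sin(x / 6) * cos(y / 5) + 40 * sin((x + y) / 9))
  fr3 <- thermal_frame(array(rep(smooth, 3), c(40, 50, 3)),
                       matrix(22, 40, 50))
  w_fwd <- warp_thermal(fr3, H)
  w_back <- warp_thermal(w_fwd, solve(H))
  both <- !is.na(w_back$temperature) & !is.na(w_fwd$temperature)
  # erode the mask so border pixels mixing invalid zeros are excluded
  er <- both
  for (d in list(c(1, 0), c(-1, 0), c(0, 1), c(0, -1))) {
    er <- er & canopy3d:::shift_pad(both, d[1], d[2], FALSE)
  }
  g1 <- to_gray(w_back$pseudo_color)
  expect_lt(mean(abs(smooth[er] - g1[er])), 2)
})

test_that("coarse registration recovers the scene homography", {
  rig <- test_rig()
  sc <- cached_scene(seed = 3)
  co <- coarse_register(sc$thermal, sc$pair, rig, illumination_klx = 70)
  src <- co$projected_thermal[co$inliers, , drop = FALSE]
  err <- homography_transformation_error(
    src, apply_homography(sc$truth$H_thermal_to_color, src), co$H)
  expect_lt(err, 0.5)
  expect_gte(co$stage_counts$epipolar, 4)
  expect_equal(co$direction, "thermal->color")

  # blank canopy (all-soil scene) fails with a registration error
  sc_bare <- render_canopy_scene(rig, seed = 2, n_leaves = 0)
  expect_error(coarse_register(sc_bare$thermal, sc_bare$pair, rig,
                               illumination_klx = 70), "canopy mask")
})

test_that("degenerate co-located rig yields an identity homography", {
  rig <- test_rig(thermal_offset_mm = c(0, 0, 0),
                  thermal_rot_deg = c(0, 0, 0))
  sc <- render_canopy_scene(rig, seed = 6)
  co <- coarse_register(sc$thermal, sc$pair, rig, illumination_klx = 70)
  # identity in the harmonized frame: H maps thermal pixels to themselves
  pts <- cbind(c(10, 80, 40), c(10, 30, 60))
  mapped <- apply_homography(co$H, pts)
  expect_lt(max(abs(mapped - pts)), 0.5)
})

test_that("fine registration compensates a planted bias and never loses to coarse", {
  rig <- test_rig()
  sc <- cached_scene(seed = 3)
  co <- coarse_register(sc$thermal, sc$pair, rig, illumination_klx = 70)
  color_h <- canopy3d:::harmonize_image(sc$pair$left, co$harmonization)

  fi <- fine_register(co, thermal = sc$thermal, color_image = color_h,
                      search_range = 2, step = 1)
  expect_equal(fi$delta, c(0, 0))               # coarse already exact
  expect_gte(fi$ssim_score, fi$ssim_coarse)
  expect_true(all(abs(fi$delta) <= 2))

  # planted (+3, 0) bias on the projected thermal points is compensated
  # within one grid step
  biased <- cbind(co$projected_thermal[, 1] + 3, co$projected_thermal[, 2])
  fi_b <- fine_register(co, color_keypoints = co$keypoints,
                        projected_thermal_points = biased,
                        thermal = sc$thermal, color_image = color_h,
                        search_range = 4, step = 1)
  expect_lte(abs(fi_b$delta[1] - (-3)), 1)
  expect_lte(abs(fi_b$delta[2]), 1)
  expect_gte(fi_b$ssim_score, fi_b$ssim_coarse)
})
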