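test_that("rectification is a no-op for an ideal rig and aligns rotated rigs", {
  rig <- test_rig()
  sc <- cached_scene(seed = 3)
  rect <- rectify_pair(sc$pair, rig)
  expect_lt(mean(abs(to_gray(rect$pair$left) - to_gray(sc$pair$left))), 1)
  expect_equal(rect$intrinsics$baseline, 60)

  # rig with a 2 degree relative rotation: projected 3D points share rows
  # after rectification (projection through the rectified model)
  rig2 <- rig
  R <- canopy3d:::rotation_xyz(c(0, 2, 0) * pi / 180)
  rig2$left_to_right$R <- R
  rig2$left_to_right$T <- as.numeric(-R %*% c(60, 0, 0))
  rect2 <- rectify_pair(sc$pair, rig2)
  set.seed(1)
  P <- cbind(runif(50, -300, 300), runif(50, -150, 150), runif(50, 1100, 1600))
  Kn <- rect2$K_new
  proj <- function(P, K, R, T) {
    p <- K %*% (R %*% t(P) + T)
    cbind(p[1, ] / p[3, ], p[2, ] / p[3, ])
  }
  pl <- proj(P, Kn, rect2$R_rect_left, c(0, 0, 0))
  pr <- proj(P, Kn, rect2$R_rect_right %*% rig2$left_to_right$R,
             as.numeric(rect2$R_rect_right %*% rig2$left_to_right$T))
  expect_lt(max(abs(pl[, 2] - pr[, 2])), 0.5)

  bad <- rig
  bad$cameras$left$f <- 0
  expect_error(rectify_pair(sc$pair, bad), "focal")
})

test_that("SGBM recovers plane disparities and degrades gracefully", {
  rig <- test_rig()
  sc <- cached_scene(seed = 3)
  rect <- rectify_pair(sc$pair, rig)
  params <- stereo_params_for_rig(rig, c(1000, 2000))
  d <- compute_disparity(rect$pair, params)
  d_true <- rig$cameras$left$f * 60 / sc$truth$plane_depth
  ok <- is.finite(d)
  expect_gt(mean(ok), 0.8)
  expect_gte(mean(abs(d[ok] - d_true) <= 1), 0.9)

  # two-plane scene: disparity histogram is bimodal at the closed forms
  sc2 <- cached_scene(seed = 5, two_plane = TRUE, soil_depth_offset = 200)
  rect2 <- rectify_pair(sc2$pair, rig)
  d2 <- compute_disparity(rect2$pair, params)
  d_can <- rig$cameras$left$f * 60 / sc2$truth$plane_depth
  d_soil <- rig$cameras$left$f * 60 / sc2$truth$soil_depth
  v <- d2[is.finite(d2)]
  near_can <- mean(abs(v - d_can) <= 0.75)
  near_soil <- mean(abs(v - d_soil) <= 0.75)
  expect_gt(near_can, 0.1)
  expect_gt(near_soil, 0.1)
  expect_gt(near_can + near_soil, 0.9)

  # textureless pair: mostly invalid, no crash
  blank <- color_stereo_pair(array(128, c(60, 80, 3)), array(128, c(60, 80, 3)))
  db <- compute_disparity(blank, list(min_disparity = 0, num_disparities = 16,
                                      block_size = 5, uniqueness_ratio = 10,
                                      lr_max_diff = 1))
  expect_gt(mean(is.na(db)), 0.5)
})

test_that("median filter matches the brute-force oracle and preserves invalids", {
  const <- matrix(7, 6, 6)
  expect_equal(median_filter_disparity(const, 3), const)

  spike <- matrix(10, 7, 7); spike[4, 4] <- 99
  expect_equal(median_filter_disparity(spike, 3)[4, 4], 10)

  set.seed(8)
  m <- matrix(runif(81, 0, 50), 9, 9)
  m[sample(81, 15)] <- NA
  for (w in c(3, 5)) {
    expect_equal(median_filter_disparity(m, w), oracle_median_filter(m, w))
  }
  expect_true(all(is.na(median_filter_disparity(m, 3)[is.na(m)])))
  expect_error(median_filter_disparity(m, 4), "odd")

  # translation equivariance on interior rows (borders see truncated
  # windows and the wrapped row)
  shifted <- m[c(2:9, 1), ]
  expect_equal(median_filter_disparity(m, 3)[3:8, ],
               median_filter_disparity(shifted, 3)[2:7, ])
})

test_that("multi-level mean fill matches the nested-loop oracle", {
  full <- matrix(runif(100, 5, 20), 10, 10)
  expect_identical(multilevel_mean_fill(full, 4), full)

  holed <- matrix(12, 8, 8)
  holed[4:5, 4:5] <- NA
  expect_equal(multilevel_mean_fill(holed, 4), matrix(12, 8, 8))

  set.seed(13)
  for (rep in 1:10) {
    m <- matrix(runif(144, 0, 40), 12, 12)
    m[sample(144, sample(20:90, 1))] <- NA
    for (w in c(4, 8)) {
      expect_equal(multilevel_mean_fill(m, w), oracle_multilevel_fill(m, w))
    }
  }
  expect_error(multilevel_mean_fill(holed, 2), ">= 3")

  # conservative: valid set only grows, original values unchanged
  m <- matrix(runif(144, 0, 40), 12, 12)
  m[sample(144, 40)] <- NA
  out <- multilevel_mean_fill(m, 8)
  was_valid <- is.finite(m)
  expect_true(all(is.finite(out)[was_valid]))
  expect_identical(out[was_valid], m[was_valid])
})

test_that("window halving schedule makes the 4x4 initial window meaningful", {
  expect_equal(canopy3d:::fill_window_sequence(4), c(4L, 3L))
  expect_equal(canopy3d:::fill_window_sequence(3), 3L)
  expect_equal(canopy3d:::fill_window_sequence(8), c(8L, 4L, 3L))
  expect_equal(canopy3d:::fill_window_sequence(16), c(16L, 8L, 4L, 3L))
})

test_that("depth relations match direct scalar evaluation", {
  d <- matrix(c(40, NA, 0, -3, 20, 10), 2, 3)
  D <- disparity_to_depth(d, 60, 800)
  expect_equal(D[1, 1], 1200)                  # 60 * 800 / 40
  expect_true(is.na(D[2, 1]) && is.na(D[1, 2]) && is.na(D[2, 2]))
  expect_equal(D[1, 3] / D[1, 2 * 0 + 3], 1)
  # halving d doubles D
  expect_equal(disparity_to_depth(matrix(20), 60, 800)[1, 1],
               2 * disparity_to_depth(matrix(40), 60, 800)[1, 1])

  intr <- list(f = 800, cx = 3, cy = 2)
  depth <- matrix(1500, 5, 7)
  p <- reproject_to_3d(depth, intr)
  expect_equal(p$X[3, 4], 0)                   # pixel at the principal point
  expect_equal(p$Y[3, 4], 0)
  expect_equal(p$Z[3, 4], 1500)
  # random pixels equal the scalar arithmetic
  set.seed(2)
  for (i in 1:20) {
    y <- sample(0:4, 1); x <- sample(0:6, 1); Dv <- runif(1, 800, 2000)
    depth2 <- depth; depth2[y + 1, x + 1] <- Dv
    p2 <- reproject_to_3d(depth2, intr)
    expect_equal(p2$X[y + 1, x + 1], (x - 3) / 800 * Dv)
    expect_equal(p2$Y[y + 1, x + 1], (y - 2) / 800 * Dv)
  }
})

test_that("reconstruction composition recovers ground-truth 3D points", {
  rig <- test_rig()
  sc <- cached_scene(seed = 3)
  rect <- rectify_pair(sc$pair, rig)
  d <- compute_disparity(rect$pair, stereo_params_for_rig(rig, c(1000, 2000)))
  d <- median_filter_disparity(d, 3)
  depth <- disparity_to_depth(d, rect$intrinsics$baseline, rect$intrinsics$f)
  pts <- reproject_to_3d(depth, rect$intrinsics)
  # plane scene: the valid reconstruction concentrates on the plane depth
  # (subpixel disparity quantization maps to ~1-2% depth noise at this
  # geometry; a few ambiguous-texture pixels can sit far off)
  ok <- is.finite(pts$Z)
  relerr <- abs(pts$Z[ok] - sc$truth$plane_depth) / sc$truth$plane_depth
  expect_gte(mean(relerr <= 0.025), 0.9)
  expect_lt(median(relerr), 0.02)
})
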