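test_that("harmonization resizes bicubically and validates the crop window", {
  img <- array(runif(288 * 384 * 3, 0, 255), c(288, 384, 3))
  expect_equal(harmonize_color_to_thermal(img, 1, c(0, 0)), img)

  const <- array(87, c(720, 1280, 3))
  out <- harmonize_color_to_thermal(const, 0.45, c(100, 20))
  expect_equal(dim(out), c(288L, 384L, 3L))
  expect_true(max(abs(out - 87)) < 1e-9)

  expect_error(harmonize_color_to_thermal(const, 0.3, c(100, 20)), "exceeds")
})

test_that("harmonized checkerboard pitch matches the thermal render within 1 px", {
  rig <- test_rig()
  fx <- make_checkerboard_fixture(square_mm = 30, layout = c(7, 9),
                                  depth = 1300, rig = rig)
  harm <- canopy3d:::harmonization_from_calib(rig$cameras$left,
                                              rig$cameras$thermal)
  harm_img <- canopy3d:::harmonize_image(fx$color, harm)
  # autocorrelation-peak pitch oracle on a mid-row profile
  pitch_of <- function(gray) {
    row <- gray[round(nrow(gray) / 2), ]
    row <- row - mean(row)
    ac <- sapply(2:(length(row) - 2), function(lag) {
      sum(row[1:(length(row) - lag)] * row[(lag + 1):length(row)])
    })
    which(diff(sign(diff(ac))) == -2)[1] + 1  # first local maximum
  }
  p_color <- pitch_of(to_gray(harm_img))
  p_thermal <- pitch_of(to_gray(fx$thermal))
  expected <- 30 * rig$cameras$thermal$f / 1300
  expect_lt(abs(p_color - p_thermal), 1 + 1e-9)
  expect_lt(abs(p_color - expected), 1.5)
})

test_that("Laplacian sharpening matches the explicit convolution oracle", {
  # constant image unchanged
  const <- matrix(120, 8, 8)
  expect_equal(sharpen_laplacian(const), const)

  # impulse response equals hand-evaluated kernel arithmetic with clipping
  imp <- matrix(0, 5, 5); imp[3, 3] <- 10
  lap <- matrix(c(0, 1, 0, 1, -4, 1, 0, 1, 0), 3, 3, byrow = TRUE)
  expected <- pmin(pmax(imp - oracle_convolve2d(imp, lap), 0), 255)
  expect_equal(sharpen_laplacian(imp), expected)
  expect_equal(sharpen_laplacian(imp)[3, 3], 50)  # 10 - (-4*10)

  # step edge: contrast across the edge strictly increases (oracle-checked)
  step <- matrix(rep(c(40, 40, 200, 200, 200), each = 5), 5, 5)
  sharp <- sharpen_laplacian(step)
  expect_equal(sharp, pmin(pmax(step - oracle_convolve2d(step, lap), 0), 255))
  expect_gt(sharp[3, 3] - sharp[3, 2], step[3, 3] - step[3, 2])
})

test_that("HSV canopy mask is a channel-interval conjunction", {
  thr <- segmentation_thresholds(HL = 35, HU = 100, SL = 35)
  px <- function(r, g, b) array(c(r, g, b), c(1, 1, 3))
  expect_equal(canopy_mask_hsv(px(0, 200, 0), thr)[1, 1], 1)    # green
  expect_equal(canopy_mask_hsv(px(200, 0, 0), thr)[1, 1], 0)    # red hue
  # green hue but saturation below SL fails the conjunction
  expect_equal(canopy_mask_hsv(px(180, 200, 180), thr)[1, 1], 0)
  # V bound participates too
  thr_v <- segmentation_thresholds(HL = 35, HU = 100, SL = 35, VL = 150, VU = 255)
  expect_equal(canopy_mask_hsv(px(0, 100, 0), thr_v)[1, 1], 0)
})

test_that("mask widening is monotone and on-scene recall/precision hold", {
  sc <- cached_scene(seed = 4)
  harm <- sc$truth$harmonization
  left_h <- canopy3d:::harmonize_image(sc$pair$left, harm)
  thr <- segmentation_thresholds(35, 100, 35)
  m1 <- canopy_mask_hsv(left_h, thr)
  # widening any interval never shrinks the mask
  wider <- list(segmentation_thresholds(20, 120, 35),
                segmentation_thresholds(35, 100, 10),
                segmentation_thresholds(35, 100, 35, VL = 0, VU = 255))
  for (tw in wider) {
    mw <- canopy_mask_hsv(left_h, tw)
    expect_true(all(mw >= m1))
  }
  # labels on the thermal raster == harmonized raster (same geometry for a
  # co-sized render); use scene truth labels mapped through the truth H
  truth_mask <- sc$truth$labels_left
  # sample the left-raster truth at harmonized pixel preimages
  hh <- dim(left_h)[1]; ww <- dim(left_h)[2]
  xg <- rep(0:(ww - 1), each = hh); yg <- rep(0:(hh - 1), times = ww)
  sx <- (xg + harm$offset[1]) / harm$scale
  sy <- (yg + harm$offset[2]) / harm$scale
  lab <- matrix(truth_mask[cbind(pmin(pmax(round(sy), 0), nrow(truth_mask) - 1) + 1,
                                 pmin(pmax(round(sx), 0), ncol(truth_mask) - 1) + 1)],
                hh, ww)
  is_canopy <- lab == "canopy"
  recall <- sum(m1 == 1 & is_canopy) / sum(is_canopy)
  precision <- sum(m1 == 1 & is_canopy) / sum(m1 == 1)
  expect_gt(recall, 0.95)
  expect_gt(precision, 0.95)
})

test_that("saturation lower bound follows the illumination regime", {
  expect_equal(select_saturation_lower(mode = "direct"), 35)
  expect_equal(select_saturation_lower(mode = "shade"), 60)
  expect_equal(select_saturation_lower(70, "auto"), 35)   # 70 klx >= 50 klx
  expect_equal(select_saturation_lower(30, "auto"), 60)
  expect_error(select_saturation_lower(NULL, "auto"), "mode")
})

test_that("apply_mask zeroes outside, preserves inside, and is idempotent", {
  img <- array(runif(60, 0, 255), c(4, 5, 3))
  ones <- matrix(1, 4, 5)
  zeros <- matrix(0, 4, 5)
  expect_equal(apply_mask(img, ones), img)
  expect_true(all(apply_mask(img, zeros) == 0))
  checker <- matrix(rep_len(c(1, 0), 20), 4, 5)
  const <- array(9, c(4, 5, 3))
  masked <- apply_mask(const, checker)
  expect_equal(sum(masked[, , 1] != 0), sum(checker))
  expect_equal(apply_mask(masked, checker), masked)
  expect_error(apply_mask(img, matrix(1, 5, 4)), "dimensions")
})
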