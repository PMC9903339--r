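test_that("dry reference is air temperature plus the offset", {
  expect_equal(dry_reference(25.0), 32.0)
  expect_equal(dry_reference(29.54), 36.54)
  expect_error(dry_reference(NaN), "finite")
  expect_error(dry_reference(NA_real_), "finite")
})

test_that("wet reference averages valid ROI temperatures", {
  g <- matrix(18.0, 6, 8)
  expect_equal(wet_reference_from_roi(g, c(1, 1, 3, 3)), 18.0)
  g2 <- matrix(NA_real_, 4, 4)
  g2[1, 1:3] <- c(18, 19, 20)
  expect_equal(wet_reference_from_roi(g2, c(0, 0, 2, 0)), 19.0)
  expect_error(wet_reference_from_roi(g2, c(0, 2, 3, 3)), "no valid")
  # 3D-box variant on a cloud
  cl <- fused_point_cloud(x = c(0, 10, 100), y = c(0, 0, 0), z = c(5, 5, 5),
                          r = 1:3, g = 1:3, b = 1:3,
                          temperature = c(18, 20, 30))
  expect_equal(wet_reference_from_roi(cl, list(x = c(-5, 15), y = c(-1, 1),
                                               z = c(0, 10))), 19.0)
})

test_that("point CWSI follows the normalized index with clamping", {
  refs <- reference_temperatures(T_wet = 20, T_air = 25)  # T_dry = 32
  expect_equal(as.numeric(compute_cwsi_point(20, refs)), 0)
  expect_equal(as.numeric(compute_cwsi_point(32, refs)), 1)
  expect_equal(as.numeric(compute_cwsi_point(26, refs)), 0.5)
  v <- compute_cwsi_point(c(18, 26, 35), refs)
  expect_equal(as.numeric(v), c(0, 0.5, 1))
  expect_equal(attr(v, "n_clamped"), 2L)
  expect_error(reference_temperatures(T_wet = 35, T_air = 25), "exceed")
})

test_that("CWSI is monotone in canopy temperature and affine invariant", {
  refs <- reference_temperatures(21, 29.5)
  tc <- seq(21.5, 36, by = 0.25)
  v <- as.numeric(compute_cwsi_point(tc, refs))
  expect_true(all(diff(v[tc < 36.49 & tc > 21]) >= 0))
  unclamped <- tc > 21 & tc < 36.5
  expect_true(all(diff(v[unclamped]) > 0))
  for (c0 in c(-3, 2.7)) {
    refs2 <- reference_temperatures(21 + c0, 29.5 + c0)
    expect_equal(as.numeric(compute_cwsi_point(tc + c0, refs2)), v)
  }
})

test_that("field CWSI reports clamping and averages correctly", {
  refs <- reference_temperatures(20, 25)    # T_dry = 32
  cl <- fused_point_cloud(x = 1:4, y = rep(0, 4), z = rep(1, 4),
                          r = rep(0, 4), g = rep(0, 4), b = rep(0, 4),
                          temperature = c(20, 20, 32, 32))
  f <- compute_cwsi_field(cl, refs)
  expect_equal(f$cwsi, c(0, 0, 1, 1))
  s <- canopy_mean_cwsi(f, "2022-04-26T13:00:00", T_air = 25)
  expect_equal(s$mean_cwsi, 0.5)
  expect_equal(s$n, 4L)

  const <- cl; const$temperature <- rep(26, 4); class(const) <- class(cl)
  fc <- compute_cwsi_field(const, refs)
  expect_true(all(fc$cwsi == 0.5))
})

test_that("planted CWSI fields are recovered from scene temperatures", {
  rms <- sapply(1:3, function(s) {
    sc <- render_canopy_scene(test_rig(), seed = s,
                              temp = list(noise_sd = 0.1))
    cl <- scene_truth_cloud(sc)
    keep <- attr(cl, "labels") == "canopy"
    truth <- attr(cl, "cwsi_true")[keep]
    sub <- cl[keep, ]; class(sub) <- class(cl)
    f <- compute_cwsi_field(sub, sc$truth$refs)
    sqrt(mean((f$cwsi - truth)^2))
  })
  expect_true(all(rms <= 0.02))
  # at sigma = 0.5 degC the recovery loosens but stays within 0.1 RMS
  sc <- render_canopy_scene(test_rig(), seed = 9,
                            temp = list(noise_sd = 0.5))
  cl <- scene_truth_cloud(sc)
  keep <- attr(cl, "labels") == "canopy"
  f <- compute_cwsi_field(cl[keep, ] |> structure(class = class(cl)),
                          sc$truth$refs)
  expect_lte(sqrt(mean((f$cwsi - attr(cl, "cwsi_true")[keep])^2)), 0.1)
})

test_that("time-series assembly joins environment records deterministically", {
  s <- rbind(
    canopy_mean_cwsi(compute_cwsi_field(
      fused_point_cloud(1, 1, 1, 0, 0, 0, 26),
      reference_temperatures(20, 25)), "2022-04-26 11:00:00",
      group = "well_watered"),
    canopy_mean_cwsi(compute_cwsi_field(
      fused_point_cloud(1, 1, 1, 0, 0, 0, 29),
      reference_temperatures(20, 25)), "2022-04-26 11:00:00",
      group = "stressed"),
    canopy_mean_cwsi(compute_cwsi_field(
      fused_point_cloud(1, 1, 1, 0, 0, 0, 23),
      reference_temperatures(20, 25)), "2022-04-26 13:00:00",
      group = "well_watered"),
    canopy_mean_cwsi(compute_cwsi_field(
      fused_point_cloud(1, 1, 1, 0, 0, 0, 31),
      reference_temperatures(20, 25)), "2022-04-26 13:00:00",
      group = "stressed"))
  env <- data.frame(time = c("2022-04-26 11:02:00", "2022-04-26 12:58:00"),
                    t_air = c(29.54, 31.05),
                    illumination_klx = c(72.4, 69.4))
  tab <- assemble_time_series(s, env, tolerance_min = 5)
  expect_equal(nrow(tab), 2L)
  expect_equal(names(tab),
               c("time", "cwsi_well_watered", "cwsi_stressed", "t_air",
                 "illumination_klx"))
  expect_equal(tab$t_air, c(29.54, 31.05))
  expect_equal(tab$cwsi_stressed, c(0.75, 11 / 12))

  # out-of-tolerance rows keep NA env fields with a warning
  env_far <- data.frame(time = "2022-04-26 09:00:00", t_air = 25,
                        illumination_klx = 40)
  w <- testthat::capture_warnings(tab2 <- assemble_time_series(s, env_far))
  expect_true(any(grepl("no environment", w)))
  expect_true(all(is.na(tab2$t_air)))

  # planted diurnal peaks: argmax of the assembled series matches
  times <- sprintf("2022-04-26 %02d:00:00", 8:17)
  peak_at <- 5  # 12:00
  vals <- dnorm(seq_along(times), peak_at, 2)
  vals <- 0.2 + 0.6 * vals / max(vals)
  sums <- do.call(rbind, lapply(seq_along(times), function(i) {
    data.frame(timestamp = times[i], group = "well_watered",
               mean_cwsi = vals[i], n = 10, T_air = NA, illumination_klx = NA)
  }))
  tab3 <- assemble_time_series(sums, NULL)
  expect_equal(which.max(tab3$cwsi_well_watered), peak_at)
})
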