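test_that("fusion emits one point per jointly valid pixel", {
  Z <- matrix(c(1200, NA, 1300, 1250), 2, 2)
  pts <- list(X = Z * 0.1, Y = Z * 0.2, Z = Z)
  col <- array(seq_len(12), c(2, 2, 3))
  temps <- matrix(c(24, 25, NA, 26), 2, 2)
  cl <- fuse(pts, col, temps)
  # valid depth AND valid temperature: pixels (1,1) and (2,2)
  expect_equal(nrow(cl), 2L)
  expect_equal(sort(cl$temperature), c(24, 26))
  expect_equal(cl$z[cl$temperature == 24], 1200)
  expect_equal(cl$r[cl$temperature == 24], col[1, 1, 1])
  expect_equal(nrow(cl), sum(is.finite(Z) & is.finite(temps)))
  expect_error(fuse(pts, col, matrix(20, 3, 2)), "aligned")

  # single-pixel case
  cl1 <- fuse(list(X = matrix(1), Y = matrix(2), Z = matrix(1500)),
              array(c(10, 20, 30), c(1, 1, 3)), matrix(22.5))
  expect_equal(nrow(cl1), 1L)
  expect_equal(cl1$temperature, 22.5)
  expect_equal(c(cl1$r, cl1$g, cl1$b), c(10, 20, 30))
})

test_that("HSV point filter keeps canopy-coloured points", {
  green <- canopy3d:::hsv180_to_rgb(rep(65, 80), rep(180, 80), rep(170, 80))
  soil <- canopy3d:::hsv180_to_rgb(rep(12, 20), rep(110, 20), rep(110, 20))
  cl <- fused_point_cloud(
    x = seq_len(100), y = rep(0, 100), z = rep(1200, 100),
    r = c(green$r, soil$r), g = c(green$g, soil$g), b = c(green$b, soil$b),
    temperature = rep(25, 100))
  out <- filter_canopy_points_hsv(cl, segmentation_thresholds(35, 100, 35))
  expect_equal(nrow(out), 80L)
  expect_true(all(out$x <= 80))
  # all-green cloud is untouched; empty cloud passes through
  all_green <- cl[1:80, ]; class(all_green) <- class(cl)
  expect_equal(nrow(filter_canopy_points_hsv(all_green)), 80L)
  expect_equal(nrow(filter_canopy_points_hsv(fused_point_cloud())), 0L)
})

test_that("statistical outlier removal agrees exactly with brute force", {
  # regular 10x10 grid (5 mm spacing) + one far point
  g <- expand.grid(x = seq(0, 45, 5), y = seq(0, 45, 5))
  cl <- fused_point_cloud(x = c(g$x, 500), y = c(g$y, 500),
                          z = rep(1200, 101),
                          r = rep(100, 101), g = rep(200, 101),
                          b = rep(100, 101), temperature = rep(25, 101))
  out <- remove_statistical_outliers(cl, 50, 0.5)
  expect_equal(nrow(out), 100L)
  expect_false(any(out$x == 500))

  # random clouds: kept set identical to the quadratic-time oracle
  set.seed(21)
  for (rep in 1:3) {
    n <- 300
    cl2 <- fused_point_cloud(
      x = c(rnorm(n - 10, 0, 40), runif(10, 200, 400)),
      y = rnorm(n, 0, 40), z = 1200 + rnorm(n, 0, 30),
      r = rep(0, n), g = rep(0, n), b = rep(0, n),
      temperature = rep(25, n))
    kept_oracle <- oracle_sor_kept(cl2, 30, 0.5)
    out2 <- remove_statistical_outliers(cl2, 30, 0.5)
    expect_equal(as.integer(rownames(out2)), kept_oracle)
  }

  small <- cl[1:10, ]; class(small) <- class(cl)
  expect_error(remove_statistical_outliers(small, 50), "smaller k")
})

test_that("k-means temperature cleaning keeps the majority/cooler cluster", {
  set.seed(6)
  cool <- 25 + runif(100, -0.2, 0.2)
  hot <- 40 + runif(20, -0.2, 0.2)
  cl <- fused_point_cloud(x = seq_len(120), y = rep(0, 120), z = rep(1200, 120),
                          r = 0 * seq_len(120), g = 0 * seq_len(120),
                          b = 0 * seq_len(120),
                          temperature = c(cool, hot))
  res <- kmeans_temperature_clean(cl)
  expect_equal(nrow(res$cloud), 100L)
  expect_true(all(res$cloud$temperature < 30))
  # assignment agrees with the exhaustive 1-D threshold oracle
  thr <- oracle_1d_2means(cl$temperature)
  expect_true(all(res$cloud$temperature <= thr))
  expect_equal(sum(cl$temperature <= thr), 100L)

  # identical temperatures: degenerate rule keeps everything
  same <- cl; same$temperature <- rep(25, 120); class(same) <- class(cl)
  res2 <- kmeans_temperature_clean(same)
  expect_true(res2$degenerate)
  expect_equal(nrow(res2$cloud), 120L)

  # equal cluster sizes: cooler cluster kept
  tie <- fused_point_cloud(x = 1:20, y = rep(0, 20), z = rep(0, 20),
                           r = rep(0, 20), g = rep(0, 20), b = rep(0, 20),
                           temperature = c(rep(20, 10), rep(35, 10)))
  res3 <- kmeans_temperature_clean(tie)
  expect_equal(nrow(res3$cloud), 10L)
  expect_true(all(res3$cloud$temperature == 20))
})

test_that("cleaning chain counts are non-increasing and idempotent stages", {
  sc <- cached_scene(seed = 4, artifact_edge_px = 1)
  cl <- scene_truth_cloud(sc)
  res <- clean_point_cloud(cl, config = default_config())
  cnt <- unlist(res$report$counts)
  expect_true(all(diff(cnt) <= 0))
  # HSV and k-means stages are idempotent on their own output
  again_hsv <- filter_canopy_points_hsv(res$cloud)
  expect_equal(nrow(again_hsv), nrow(res$cloud))
  km2 <- kmeans_temperature_clean(res$cloud)
  # second k-means removes at most a sliver (idempotence on cleaned output)
  expect_gte(nrow(km2$cloud) / nrow(res$cloud), 0.5)
})

test_that("planted hot-edge artefacts are removed, canopy kept", {
  removed_art <- kept_can <- numeric(0)
  for (s in 1:3) {
    sc <- render_canopy_scene(test_rig(), seed = s, artifact_edge_px = 1,
                              artifact_temp_gap = 10)
    cl <- scene_truth_cloud(sc)
    lab <- attr(cl, "labels")
    sub <- cl[lab != "soil", ]; class(sub) <- class(cl)
    lab <- lab[lab != "soil"]
    res <- kmeans_temperature_clean(sub)
    kept <- seq_len(nrow(sub)) %in% match(rownames(res$cloud), rownames(sub))
    removed_art <- c(removed_art, mean(!kept[lab == "artifact"]))
    kept_can <- c(kept_can, mean(kept[lab == "canopy"]))
  }
  expect_true(all(removed_art >= 0.95))
  expect_true(all(kept_can >= 0.95))
})
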