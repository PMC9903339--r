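#' Fuse geometry, colour and temperature into a point cloud
#'
#' One point per pixel that has both a valid depth/3D coordinate and a
#' valid temperature; the point carries that pixel's XYZ (mm), RGB and
#' temperature. The three rasters must be pixel-aligned (the rectified-left
#' raster, with the temperature grid warped by the fine registration and
#' expanded to that raster).
#'
#' @param points3d list of `X`, `Y`, `Z` matrices from [reproject_to_3d()].
#' @param color colour array aligned to the same raster (0--255).
#' @param temperature temperature matrix aligned to the same raster
#'   (`NA` = invalid).
#' @return a [fused_point_cloud()].
#' @export
fuse <- function(points3d, color, temperature) {
  d <- dim(points3d$Z)
  if (!all(dim(color)[1:2] == d) || !all(dim(temperature) == d)) {
    stopf("fuse: rasters are not pixel-aligned (depth %dx%d, color %dx%d, temperature %dx%d)",
          d[1], d[2], dim(color)[1], dim(color)[2],
          nrow(temperature), ncol(temperature))
  }
  ok <- is.finite(points3d$Z) & is.finite(temperature)
  idx <- which(ok)
  fused_point_cloud(
    x = points3d$X[idx], y = points3d$Y[idx], z = points3d$Z[idx],
    r = color[, , 1][idx], g = color[, , 2][idx], b = color[, , 3][idx],
    temperature = temperature[idx])
}

# Expand a temperature grid living on the harmonized (thermal-geometry)
# raster to the full rectified-left colour raster via the inverse of the
# harmonization affine, nearest-neighbour so quantization is preserved.
temperature_on_color_raster <- function(temp_h, harm, color_dim) {
  h <- color_dim[1]; w <- color_dim[2]
  xg <- rep(0:(w - 1), each = h)
  yg <- rep(0:(h - 1), times = w)
  hx <- harm$scale * xg - harm$offset[1]
  hy <- harm$scale * yg - harm$offset[2]
  matrix(nearest_sample(temp_h, hx, hy), h, w)
}

#' HSV canopy filter on a point cloud
#'
#' Keeps points whose RGB colour passes the same HSV interval predicate as
#' [canopy_mask_hsv()].
#'
#' @param cloud a [fused_point_cloud()].
#' @param thresholds a [segmentation_thresholds()].
#' @export
filter_canopy_points_hsv <- function(cloud, thresholds = segmentation_thresholds()) {
  stopifnot(inherits(cloud, "fused_point_cloud"))
  if (!nrow(cloud)) return(cloud)
  t <- thresholds
  hsv <- rgb_to_hsv180(cloud$r, cloud$g, cloud$b)
  keep <- hsv$h >= t$HL & hsv$h <= t$HU &
    hsv$s >= t$SL & hsv$s <= t$SU &
    hsv$v >= t$VL & hsv$v <= t$VU
  cloud[keep, , drop = FALSE]
}

#' Statistical outlier removal
#'
#' For each point, the mean Euclidean distance to its `k_neighbors` nearest
#' neighbours is computed (exactly); points whose mean distance exceeds
#' `mu + std_ratio * sigma` of the global distribution of these means are
#' removed.
#'
#' @param cloud a [fused_point_cloud()] with more than `k_neighbors` points.
#' @param k_neighbors neighbourhood size (default 50).
#' @param std_ratio standard-deviation multiplier (default 0.5).
#' @return the filtered cloud; removed count and the bound in
#'   `attr(, "outlier_stats")`.
#' @export
remove_statistical_outliers <- function(cloud, k_neighbors = 50, std_ratio = 0.5) {
  stopifnot(inherits(cloud, "fused_point_cloud"))
  n <- nrow(cloud)
  if (n <= k_neighbors) {
    stopf("cloud has %d points but k_neighbors = %d; use a smaller k (< n)",
          n, k_neighbors)
  }
  md <- knn_mean_dist_cpp(cloud$x, cloud$y, cloud$z, as.integer(k_neighbors))
  mu <- mean(md); sg <- sd(md)
  bound <- mu + std_ratio * sg
  keep <- md <= bound
  out <- cloud[keep, , drop = FALSE]
  attr(out, "outlier_stats") <- list(mu = mu, sigma = sg, bound = bound,
                                     removed = sum(!keep))
  out
}

#' k-means temperature cleaning
#'
#' Splits the cloud into two clusters by 1-D k-means on temperature and
#' keeps the larger cluster (registration artefacts pick up the hotter
#' soil temperature and form the smaller, hotter cluster). Initialization
#' is deterministic -- centres at the 10th and 90th temperature
#' percentiles, then Lloyd iterations to 1e-6 -- so the `seed` argument is
#' accepted for interface uniformity but has no effect. When the
#' temperature spread is below `degenerate_spread` (0.2 degC, two
#' quantization steps) the cloud is returned unchanged. Equal cluster
#' sizes keep the cooler-mean cluster.
#'
#' @param cloud a non-empty [fused_point_cloud()].
#' @param k number of clusters (fixed at 2).
#' @param seed unused; see Details.
#' @param degenerate_spread spread threshold (degC) below which no
#'   clustering is attempted.
#' @return list: `cloud` (the kept points), `clusters` (data frame of
#'   cluster mean temperature, size and whether kept), `degenerate`.
#' @export
kmeans_temperature_clean <- function(cloud, k = 2, seed = 1,
                                     degenerate_spread = 0.2) {
  stopifnot(inherits(cloud, "fused_point_cloud"), k == 2)
  if (!nrow(cloud)) stopf("kmeans_temperature_clean: empty cloud")
  temps <- cloud$temperature
  if (diff(range(temps)) < degenerate_spread) {
    return(list(cloud = cloud,
                clusters = data.frame(mean_temp = mean(temps),
                                      size = length(temps), kept = TRUE),
                degenerate = TRUE))
  }
  centers <- unname(quantile(temps, c(0.1, 0.9)))
  if (centers[1] == centers[2]) centers <- range(temps)
  for (it in 1:100) {
    assign <- ifelse(abs(temps - centers[1]) <= abs(temps - centers[2]), 1L, 2L)
    new_centers <- c(mean(temps[assign == 1L]), mean(temps[assign == 2L]))
    if (any(is.nan(new_centers))) {
      new_centers[is.nan(new_centers)] <- centers[is.nan(new_centers)]
    }
    if (max(abs(new_centers - centers)) < 1e-6) { centers <- new_centers; break }
    centers <- new_centers
  }
  assign <- ifelse(abs(temps - centers[1]) <= abs(temps - centers[2]), 1L, 2L)
  sizes <- c(sum(assign == 1L), sum(assign == 2L))
  means <- c(mean(temps[assign == 1L]), mean(temps[assign == 2L]))
  keep_cluster <- if (sizes[1] != sizes[2]) {
    which.max(sizes)
  } else {
    which.min(means)   # tie: canopy is the cooler class
  }
  list(cloud = cloud[assign == keep_cluster, , drop = FALSE],
       clusters = data.frame(mean_temp = means, size = sizes,
                             kept = seq_len(2) == keep_cluster),
       degenerate = FALSE)
}

#' Three-step point-cloud optimization
#'
#' Runs the cleaning chain -- HSV canopy filter, statistical outlier
#' removal, k-means temperature cleaning -- and audits the per-stage point
#' counts in a `cleaning_report`.
#'
#' @param cloud a [fused_point_cloud()].
#' @param thresholds a [segmentation_thresholds()].
#' @param config a `pipeline_config` (cleaning parameters).
#' @return list: `cloud`, `report` (class `cleaning_report`).
#' @export
clean_point_cloud <- function(cloud, thresholds = segmentation_thresholds(),
                              config = default_config()) {
  counts <- list(input = nrow(cloud))
  c1 <- filter_canopy_points_hsv(cloud, thresholds)
  counts$hsv_filter <- nrow(c1)
  c2 <- if (nrow(c1) > config$cleaning$outlier_k) {
    remove_statistical_outliers(c1, config$cleaning$outlier_k,
                                config$cleaning$outlier_std_ratio)
  } else c1
  counts$outlier_removal <- nrow(c2)
  km <- if (nrow(c2)) {
    kmeans_temperature_clean(c2, 2, config$cleaning$kmeans_seed,
                             config$cleaning$degenerate_spread)
  } else list(cloud = c2, clusters = NULL, degenerate = TRUE)
  counts$kmeans <- nrow(km$cloud)
  report <- structure(list(counts = counts, clusters = km$clusters,
                           degenerate = km$degenerate),
                      class = "cleaning_report")
  list(cloud = km$cloud, report = report)
}

#' @export
print.cleaning_report <- function(x, ...) {
  cat("<cleaning_report>\n")
  cat(sprintf("  input:            %d\n", x$counts$input))
  cat(sprintf("  HSV filter:       %d\n", x$counts$hsv_filter))
  cat(sprintf("  outlier removal:  %d\n", x$counts$outlier_removal))
  cat(sprintf("  k-means:          %d\n", x$counts$kmeans))
  if (!is.null(x$clusters)) {
    for (i in seq_len(nrow(x$clusters))) {
      cat(sprintf("  cluster %d: %.2f degC, %d points%s\n", i,
                  x$clusters$mean_temp[i], x$clusters$size[i],
                  if (x$clusters$kept[i]) " (kept)" else ""))
    }
  }
  invisible(x)
}
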