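#' Homography transformation error
#'
#' Mean Euclidean distance (px) between the `H`-mapped source points and
#' their destinations; the residual the registration chain reports.
#'
#' @param src,dst `n x 2` matrices of corresponding points (n >= 1).
#' @param H 3x3 homography mapping src to dst.
#' @export
homography_transformation_error <- function(src, dst, H) {
  src <- matrix(as.matrix(src), ncol = 2)
  dst <- matrix(as.matrix(dst), ncol = 2)
  if (!nrow(src)) stopf("homography_transformation_error: empty point set")
  stopifnot(nrow(src) == nrow(dst))
  mean(reprojection_errors(H, src, dst))
}

#' Control point error
#'
#' Mean Euclidean distance (px) between manually (or generator-) marked
#' control points on the colour image and on the transformed thermal
#' image.
#'
#' @param color_points,thermal_points `n x 2` matrices (n >= 1).
#' @export
control_point_error <- function(color_points, thermal_points) {
  a <- matrix(as.matrix(color_points), ncol = 2)
  b <- matrix(as.matrix(thermal_points), ncol = 2)
  if (!nrow(a)) stopf("control_point_error: empty point set")
  stopifnot(nrow(a) == nrow(b))
  mean(sqrt(rowSums((a - b)^2)))
}

#' Feature-count statistics before/after canopy extraction
#'
#' Column means of matched-feature counts before and after canopy masking,
#' with the relative gain. `percent_increase` is the exact-arithmetic gain
#' of the means; `percent_increase_printed` follows the tabular reporting
#' convention of deriving the summary row from the column means rounded
#' half-up at the printed precision (`digits`), which is how such tables
#' usually print their average row. Records with a zero before-count get an
#' undefined per-record increase (`NA`, flagged in `n_undefined`).
#'
#' @param before,after integer vectors of matched-feature counts (>= 1
#'   record).
#' @param digits printed precision of the reporting convention.
#' @return list: `mean_before`, `mean_after`, `percent_increase`,
#'   `percent_increase_printed`, `per_record_increase`, `n_undefined`.
#' @export
batch_feature_count_stats <- function(before, after, digits = 1) {
  stopifnot(length(before) >= 1, length(before) == length(after))
  mb <- mean(before); ma <- mean(after)
  per <- ifelse(before > 0, (after - before) / before * 100, NA_real_)
  mb_r <- round_half_up(mb, digits)
  ma_r <- round_half_up(ma, digits)
  list(mean_before = mb, mean_after = ma,
       percent_increase = (ma - mb) / mb * 100,
       percent_increase_printed = round_half_up((ma_r - mb_r) / mb_r * 100,
                                                digits),
       per_record_increase = per,
       n_undefined = sum(is.na(per)))
}

#' Arithmetic mean of a reported table column
#'
#' @param values numeric vector (>= 1 value).
#' @export
table_mean <- function(values) {
  if (!length(values)) stopf("table_mean: empty input")
  mean(values)
}

#' Bundled registration benchmark
#'
#' A 30-sample potato-plant benchmark distributed with the package:
#' matched-feature counts before and after green-canopy extraction,
#' homography transformation errors (px) and control-point errors (px) of
#' the registered thermal/colour image pairs.
#'
#' @return data frame with columns `sample`, `features_before`,
#'   `features_after`, `homography_error_px`, `control_point_error_px`.
#' @export
registration_benchmark <- function() {
  path <- system.file("extdata", "registration_benchmark.csv",
                      package = "canopy3d")
  if (path == "") stopf("bundled benchmark not found")
  read.csv(path)
}

#' Registration score of a result against scene truth
#'
#' Computes the homography transformation error on the inlier features
#' (mapped thermal back-projections vs their matched colour keypoints --
#' the optimized set), the control-point error on generator landmarks
#' (independent of the optimization), the reprojection error against the
#' scene's true homography, and the final SSIM.
#'
#' @param fine a `fine_registration_result`.
#' @param coarse the `homography_estimate` it refined (carries the inlier
#'   keypoints and projections).
#' @param truth a `scene_truth`.
#' @return list: `homography_error_px`, `control_point_error_px`,
#'   `truth_error_px`, `ssim`.
#' @export
registration_score <- function(fine, coarse, truth) {
  src <- coarse$projected_thermal[coarse$inliers, , drop = FALSE]
  dst <- coarse$keypoints[coarse$inliers, , drop = FALSE]
  he <- homography_transformation_error(src, dst, fine$H_opt)
  te <- homography_transformation_error(
    src, apply_homography(truth$H_thermal_to_color, src), fine$H_opt)
  lm <- truth$landmarks
  cpe <- if (nrow(lm$thermal)) {
    control_point_error(lm$color, apply_homography(fine$H_opt, lm$thermal))
  } else NA_real_
  list(homography_error_px = he, control_point_error_px = cpe,
       truth_error_px = te, ssim = fine$ssim_score)
}
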