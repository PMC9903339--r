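#' Stereo rectification
#'
#' Resamples the binocular pair so that corresponding points share image
#' rows. The rectifying rotation aligns the new x-axis with the baseline
#' (Bouguet-style); both views get a common focal length and principal
#' point (the means of the two cameras'), and lens distortion is removed in
#' the inverse mapping. For an ideal rig (identity rotation, purely
#' horizontal baseline, no distortion) the images pass through unchanged up
#' to resampling.
#'
#' @param pair a [color_stereo_pair()].
#' @param calib a [rig_calibration()].
#' @return list: `pair` (rectified `color_stereo_pair`), `intrinsics`
#'   (`f`, `cx`, `cy`, `baseline` of the rectified geometry, used by the
#'   depth equations), `intrinsics_left` (full camera entry),
#'   `R_rect_left`, `R_rect_right`.
#' @export
rectify_pair <- function(pair, calib) {
  stopifnot(inherits(pair, "color_stereo_pair"), inherits(calib, "rig_calibration"))
  cl <- calib$cameras$left; cr <- calib$cameras$right
  if (cl$f <= 0 || cr$f <= 0) stopf("rectify_pair: non-positive focal length")
  R <- calib$left_to_right$R
  T <- calib$left_to_right$T
  check_orthonormal(R, what = "left_to_right$R")
  C_r <- -as.numeric(t(R) %*% T)     # right camera centre in the left frame
  B <- sqrt(sum(C_r^2))
  if (B <= 0) stopf("rectify_pair: zero baseline")
  e1 <- C_r / B
  if (e1[1] < 0) e1 <- -e1           # keep +x pointing right
  e2 <- c(-e1[2], e1[1], 0)
  n2 <- sqrt(sum(e2^2))
  if (n2 < 1e-9) e2 <- c(0, 1, 0) else e2 <- e2 / n2
  # y-axis downward, orthogonal to baseline
  e3 <- c(e1[2] * e2[3] - e1[3] * e2[2],
          e1[3] * e2[1] - e1[1] * e2[3],
          e1[1] * e2[2] - e1[2] * e2[1])
  R_rect_l <- rbind(e1, e2, e3)
  # ensure proper handedness / z forward
  if (R_rect_l[3, 3] < 0) {
    R_rect_l[2, ] <- -R_rect_l[2, ]
    R_rect_l[3, ] <- -R_rect_l[3, ]
  }
  dimnames(R_rect_l) <- NULL
  R_rect_r <- R_rect_l %*% t(R)
  f_new <- (cl$f + cr$f) / 2
  cx_new <- (cl$cx + cr$cx) / 2
  cy_new <- (cl$cy + cr$cy) / 2
  K_new <- matrix(c(f_new, 0, cx_new, 0, f_new, cy_new, 0, 0, 1), 3, 3,
                  byrow = TRUE)
  warp_cam <- function(img, cam, R_rect) {
    h <- dim(img)[1]; w <- dim(img)[2]
    xg <- rep(0:(w - 1), each = h)
    yg <- rep(0:(h - 1), times = w)
    rays <- rbind((xg - cx_new) / f_new, (yg - cy_new) / f_new, 1)
    d <- t(R_rect) %*% rays
    xn <- d[1, ] / d[3, ]; yn <- d[2, ] / d[3, ]
    dist <- cam$dist
    r2 <- xn^2 + yn^2
    radial <- 1 + dist[1] * r2 + dist[2] * r2^2 + dist[5] * r2^3
    xd <- xn * radial + 2 * dist[3] * xn * yn + dist[4] * (r2 + 2 * xn^2)
    yd <- yn * radial + dist[3] * (r2 + 2 * yn^2) + 2 * dist[4] * xn * yn
    sx <- cam$f * xd + cam$cx
    sy <- cam$f * yd + cam$cy
    out <- array(0, dim = dim(img))
    for (c in 1:3) {
      v <- bilinear_sample(img[, , c], sx, sy)
      v[!is.finite(v)] <- 0
      out[, , c] <- matrix(v, h, w)
    }
    out
  }
  left_r <- warp_cam(pair$left, cl, R_rect_l)
  right_r <- warp_cam(pair$right, cr, R_rect_r)
  intr_left <- list(f = f_new, cx = cx_new, cy = cy_new,
                    width = dim(left_r)[2], height = dim(left_r)[1],
                    dist = numeric(5))
  list(pair = color_stereo_pair(left_r, right_r, pair$timestamp),
       intrinsics = list(f = f_new, cx = cx_new, cy = cy_new, baseline = B),
       intrinsics_left = intr_left,
       R_rect_left = R_rect_l, R_rect_right = R_rect_r,
       K_new = K_new)
}

#' Disparity search range for a rig and working depth range
#'
#' Chooses `min_disparity` and `num_disparities` (a multiple of 16) so the
#' search covers the given depth range (default 1.0--2.0 m, the rig's
#' working distance) at the rectified geometry.
#'
#' @param calib a [rig_calibration()].
#' @param depth_range working depth range, mm.
#' @param params optional stereo parameter list to fill in.
#' @return the parameter list with `min_disparity` / `num_disparities` set.
#' @export
stereo_params_for_rig <- function(calib, depth_range = c(1000, 2000),
                                  params = default_config()$stereo) {
  f <- (calib$cameras$left$f + calib$cameras$right$f) / 2
  dmin <- f * calib$baseline_mm / max(depth_range)
  dmax <- f * calib$baseline_mm / min(depth_range)
  params$min_disparity <- max(0L, floor(dmin) - 2L)
  span <- ceiling(dmax) + 2L - params$min_disparity
  params$num_disparities <- as.integer(ceiling(span / 16) * 16)
  params
}

#' Disparity by semi-global block matching
#'
#' Computes a subpixel disparity map `d = xl - xr` from a rectified pair:
#' block-aggregated absolute-difference costs, 8-path semi-global
#' aggregation with smoothness penalties `P1`/`P2`, winner-take-all with
#' parabolic subpixel refinement, a uniqueness check and a left-right
#' consistency check. Inconsistent or ambiguous pixels are invalid (`NA`);
#' poorly textured regions come out invalid rather than erroring.
#'
#' @param pair rectified [color_stereo_pair()] (or the list returned by
#'   [rectify_pair()]).
#' @param params stereo parameter list, see [default_config()]`$stereo`:
#'   `min_disparity`, `num_disparities` (multiple of 16), `block_size`,
#'   `p1`, `p2` (default `8*3*block^2` / `32*3*block^2`),
#'   `uniqueness_ratio`, `lr_max_diff`.
#' @return numeric matrix of disparities (px), `NA` = invalid.
#' @export
compute_disparity <- function(pair, params = default_config()$stereo) {
  if (!inherits(pair, "color_stereo_pair") && !is.null(pair$pair)) {
    pair <- pair$pair
  }
  bs <- params$block_size %||% 5
  p1 <- params$p1 %||% (8 * 3 * bs^2)
  p2 <- params$p2 %||% (32 * 3 * bs^2)
  d <- sgbm_disparity_cpp(to_gray(pair$left), to_gray(pair$right),
                          as.integer(params$min_disparity %||% 0),
                          as.integer(params$num_disparities %||% 64),
                          as.integer(bs), p1, p2,
                          as.integer(params$uniqueness_ratio %||% 10),
                          as.integer(params$lr_max_diff %||% 1))
  d[!is.finite(d)] <- NA_real_
  d
}

#' Median filtering of a disparity map
#'
#' Each valid pixel is replaced by the median of the valid values in its
#' window; invalid pixels stay invalid. Removes isolated mismatching
#' spikes.
#'
#' @param disp disparity matrix (`NA` = invalid).
#' @param window odd window width >= 3.
#' @export
median_filter_disparity <- function(disp, window = 3) {
  if (window %% 2 == 0 || window < 3) {
    stopf("median window must be odd and >= 3, got %d", window)
  }
  out <- median_filter_valid_cpp(disp, as.integer(window))
  out[!is.finite(out)] <- NA_real_
  out
}

# Window halving schedule: initial, ceil(initial/2), ... while > 3, plus a
# mandatory final 3x3 pass.
fill_window_sequence <- function(initial_window) {
  wins <- integer()
  W <- initial_window
  while (W > 3) {
    wins <- c(wins, W)
    W <- ceiling(W / 2)
  }
  c(wins, 3L)
}

# Integral-image window sums for a W x W window anchored with floor(W/2)
# pixels above/left of the target pixel.
window_sums <- function(mat, W) {
  h <- nrow(mat); w <- ncol(mat)
  ii <- matrix(0, h + 1, w + 1)
  ii[2:(h + 1), 2:(w + 1)] <- apply(apply(mat, 2, cumsum), 1, cumsum) |> t()
  a <- W %/% 2                      # pixels above/left
  y0 <- pmax(0, (0:(h - 1)) - a); y1 <- pmin(h - 1, (0:(h - 1)) - a + W - 1)
  x0 <- pmax(0, (0:(w - 1)) - a); x1 <- pmin(w - 1, (0:(w - 1)) - a + W - 1)
  # sums[y, x] over rows y0..y1, cols x0..x1 (0-based inclusive)
  ii[y1 + 2, x1 + 2, drop = FALSE] - ii[y0 + 1, x1 + 2, drop = FALSE] -
    ii[y1 + 2, x0 + 1, drop = FALSE] + ii[y0 + 1, x0 + 1, drop = FALSE]
}

#' Multi-level mean hole filling
#'
#' Fills invalid disparities with window means of the valid values,
#' iterating over a halving window schedule: `W0 = initial_window`,
#' `ceil(W0/2)`, ... ending with a mandatory 3x3 pass (the default initial
#' window 4 gives passes 4 then 3). Window sums come from sum/count
#' integral images of the fill input; even windows are anchored with
#' `floor(W/2)` pixels above/left of the target. Later (smaller-window)
#' passes overwrite earlier assignments where they have support; originally
#' valid pixels are never modified, and pixels with no valid neighbour in
#' any window stay invalid.
#'
#' @param disp disparity matrix (`NA` = invalid).
#' @param initial_window first window size, >= 3.
#' @export
multilevel_mean_fill <- function(disp, initial_window = 4) {
  if (initial_window < 3) {
    stopf("fill initial window must be >= 3, got %d", initial_window)
  }
  valid <- is.finite(disp)
  if (all(valid)) return(disp)
  vals <- disp
  vals[!valid] <- 0
  out <- disp
  for (W in fill_window_sequence(initial_window)) {
    s <- window_sums(vals, W)
    cnt <- window_sums(valid + 0, W)
    fill <- !valid & cnt > 0
    out[fill] <- s[fill] / cnt[fill]
  }
  out
}

#' Disparity to depth
#'
#' `D = B * f / d` for valid positive disparities; non-positive or invalid
#' disparities give invalid depth.
#'
#' @param disp disparity matrix (px).
#' @param baseline_mm stereo baseline, mm (> 0).
#' @param focal_px rectified focal length, px (> 0).
#' @return depth matrix in mm (`NA` = invalid).
#' @export
disparity_to_depth <- function(disp, baseline_mm, focal_px) {
  stopifnot(baseline_mm > 0, focal_px > 0)
  out <- matrix(NA_real_, nrow(disp), ncol(disp))
  ok <- is.finite(disp) & disp > 0
  out[ok] <- baseline_mm * focal_px / disp[ok]
  out
}

#' Reproject a depth map to 3D
#'
#' Pinhole back-projection per valid pixel: `Z = D`,
#' `X = (x - cx) / f * D`, `Y = (y - cy) / f * D` (left-camera frame, mm;
#' 0-based pixel coordinates).
#'
#' @param depth depth matrix, mm (`NA` = invalid).
#' @param intrinsics list with `f`, `cx`, `cy` of the rectified geometry.
#' @return list of matrices `X`, `Y`, `Z` aligned to the depth raster.
#' @export
reproject_to_3d <- function(depth, intrinsics) {
  f <- intrinsics$f; cx <- intrinsics$cx; cy <- intrinsics$cy
  stopifnot(f > 0)
  h <- nrow(depth); w <- ncol(depth)
  xg <- matrix(rep(0:(w - 1), each = h), h, w)
  yg <- matrix(rep(0:(h - 1), times = w), h, w)
  list(X = (xg - cx) / f * depth,
       Y = (yg - cy) / f * depth,
       Z = depth)
}
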