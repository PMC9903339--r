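#' Epipolar filtering of feature matches
#'
#' For a rectified pair, valid correspondences lie on (nearly) equal image
#' rows with non-negative disparity. Keeps pairs with
#' `|yl - yr| <= row_tolerance` and `xl >= xr`.
#'
#' @param matches a `feature_match_set`.
#' @param row_tolerance row difference tolerance in px.
#' @export
filter_epipolar <- function(matches, row_tolerance = 2) {
  keep <- abs(matches$yl - matches$yr) <= row_tolerance & matches$xl >= matches$xr
  out <- matches[keep, , drop = FALSE]
  attr(out, "detector") <- attr(matches, "detector")
  class(out) <- class(matches)
  out
}

# Accept a rig_calibration (left camera + baseline) or a plain list with
# f, cx, cy, baseline.
as_triangulation_intrinsics <- function(calib) {
  if (inherits(calib, "rig_calibration")) {
    cam <- calib$cameras$left
    list(f = cam$f, cx = cam$cx, cy = cam$cy, baseline = calib$baseline_mm)
  } else {
    stopifnot(all(c("f", "cx", "cy", "baseline") %in% names(calib)))
    calib
  }
}

#' Triangulate rectified matches to 3D
#'
#' Depth from the similar-triangle relation `Z = B * f / (xl - xr)`, then
#' `X = (xl - cx) / f * Z`, `Y = (yl - cy) / f * Z` (left-camera frame,
#' mm). Pairs with non-positive disparity are excluded (count recorded in
#' `attr(, "n_excluded")`), not an error.
#'
#' @param matches a `feature_match_set` in rectified coordinates.
#' @param calib a `rig_calibration` (left camera + baseline are used) or a
#'   list with `f`, `cx`, `cy`, `baseline`.
#' @return matrix `n x 3` of XYZ (mm) with the surviving match rows in
#'   `attr(, "kept")`.
#' @export
triangulate_matches <- function(matches, calib) {
  intr <- as_triangulation_intrinsics(calib)
  d <- matches$xl - matches$xr
  keep <- d > 0
  d <- d[keep]
  Z <- intr$baseline * intr$f / d
  X <- (matches$xl[keep] - intr$cx) / intr$f * Z
  Y <- (matches$yl[keep] - intr$cy) / intr$f * Z
  structure(cbind(X = X, Y = Y, Z = Z),
            kept = which(keep), n_excluded = sum(!keep))
}

#' Back-project 3D points into the thermal image
#'
#' Pinhole projection `s * p = K [R | T] (X, Y, Z, 1)'` where `R`, `T` are
#' the pose of the thermal camera relative to the (rectified) left colour
#' camera and `s` is the depth in the thermal frame. Points behind the
#' thermal camera are excluded (`attr(, "kept")` indexes survivors).
#'
#' @param world_points `n x 3` matrix, mm, left-camera frame.
#' @param calib a `rig_calibration` (uses the thermal intrinsics and
#'   `left_to_thermal`) or a list with `K`, `R`, `T`.
#' @return `n_kept x 2` matrix of 0-based thermal pixel coordinates.
#' @export
backproject_to_thermal <- function(world_points, calib) {
  if (inherits(calib, "rig_calibration")) {
    K <- intrinsic_matrix(calib$cameras$thermal)
    R <- calib$left_to_thermal$R
    T <- calib$left_to_thermal$T
  } else {
    K <- calib$K; R <- calib$R; T <- calib$T
  }
  wp <- matrix(world_points, ncol = 3)
  cam <- t(R %*% t(wp) + T)   # n x 3 in thermal frame
  keep <- cam[, 3] > 0
  cam <- cam[keep, , drop = FALSE]
  pix <- t(K %*% t(cam))
  structure(cbind(x = pix[, 1] / pix[, 3], y = pix[, 2] / pix[, 3]),
            kept = which(keep), n_excluded = sum(!keep),
            scale_s = cam[, 3])
}

# --- homography -----------------------------------------------------------

#' Apply a homography to points
#'
#' @param H 3x3 matrix.
#' @param xy `n x 2` matrix of 0-based pixel coordinates.
#' @return `n x 2` matrix of mapped coordinates.
#' @export
apply_homography <- function(H, xy) {
  xy <- matrix(xy, ncol = 2)
  p <- H %*% rbind(xy[, 1], xy[, 2], 1)
  cbind(p[1, ] / p[3, ], p[2, ] / p[3, ])
}

# Normalized DLT homography fit (least squares for n > 4).
homography_dlt <- function(src, dst) {
  n <- nrow(src)
  stopifnot(n >= 4)
  norm_pts <- function(p) {
    c0 <- colMeans(p)
    d <- sqrt(rowSums((p - rep(c0, each = nrow(p)))^2))
    s <- if (mean(d) > 1e-12) sqrt(2) / mean(d) else 1
    T <- matrix(c(s, 0, -s * c0[1], 0, s, -s * c0[2], 0, 0, 1), 3, 3, byrow = TRUE)
    list(T = T, p = cbind(s * (p[, 1] - c0[1]), s * (p[, 2] - c0[2])))
  }
  ns <- norm_pts(src); nd <- norm_pts(dst)
  s <- ns$p; d <- nd$p
  A <- matrix(0, 2 * n, 9)
  for (i in seq_len(n)) {
    X <- c(s[i, 1], s[i, 2], 1)
    A[2 * i - 1, ] <- c(-X, 0, 0, 0, d[i, 1] * X)
    A[2 * i, ] <- c(0, 0, 0, -X, d[i, 2] * X)
  }
  sv <- svd(A, nu = 0, nv = 9)
  h <- sv$v[, 9]
  H <- matrix(h, 3, 3, byrow = TRUE)
  H <- solve(nd$T) %*% H %*% ns$T
  if (abs(H[3, 3]) < 1e-12) return(NULL)
  H / H[3, 3]
}

reprojection_errors <- function(H, src, dst) {
  m <- apply_homography(H, src)
  sqrt(rowSums((m - dst)^2))
}

#' Homography estimation with RANSAC
#'
#' Seeded RANSAC over minimal 4-point samples with a normalized-DLT model,
#' followed by a least-squares refit on the consensus inlier set. The
#' returned matrix maps `src` to `dst` and is normalized to `H[3,3] = 1`.
#'
#' @param src,dst `n x 2` matrices of corresponding 0-based pixel
#'   coordinates (n >= 4).
#' @param reproj_threshold inlier reprojection threshold, px.
#' @param seed RNG seed for reproducible sampling.
#' @param max_iter iteration cap (adaptive early stop at `confidence`).
#' @param confidence target probability of an outlier-free sample.
#' @return object of class `homography_estimate`: `H`, `inliers` (indices),
#'   `residual` (mean inlier reprojection error, px).
#' @export
estimate_homography_ransac <- function(src, dst, reproj_threshold = 3,
                                       seed = 1, max_iter = 2000,
                                       confidence = 0.995) {
  src <- matrix(as.matrix(src), ncol = 2)
  dst <- matrix(as.matrix(dst), ncol = 2)
  n <- nrow(src)
  if (n < 4) stopf("homography estimation needs >= 4 point pairs, got %d", n)
  if (nrow(dst) != n) stopf("src and dst point counts differ")
  non_degenerate <- function(p) {
    # no 3 of the 4 points collinear
    for (drop in 1:4) {
      q <- p[-drop, ]
      area <- abs((q[2, 1] - q[1, 1]) * (q[3, 2] - q[1, 2]) -
                    (q[3, 1] - q[1, 1]) * (q[2, 2] - q[1, 2]))
      if (area < 1e-6) return(FALSE)
    }
    TRUE
  }
  best_inl <- integer()
  with_seed(seed, {
    iter_needed <- max_iter
    it <- 0
    while (it < min(max_iter, iter_needed)) {
      it <- it + 1
      idx <- sample.int(n, 4)
      if (!non_degenerate(src[idx, , drop = FALSE])) next
      H <- tryCatch(homography_dlt(src[idx, , drop = FALSE],
                                   dst[idx, , drop = FALSE]),
                    error = function(e) NULL)
      if (is.null(H) || abs(det(H)) < 1e-12) next
      err <- reprojection_errors(H, src, dst)
      inl <- which(err <= reproj_threshold)
      if (length(inl) > length(best_inl)) {
        best_inl <- inl
        w <- length(inl) / n
        if (w > 0) {
          iter_needed <- ceiling(log(1 - confidence) /
                                   log(max(1e-12, 1 - w^4)))
        }
      }
    }
  })
  if (length(best_inl) < 4) {
    stopf("RANSAC failed: no consensus set of >= 4 inliers (n = %d)", n)
  }
  H <- homography_dlt(src[best_inl, , drop = FALSE],
                      dst[best_inl, , drop = FALSE])
  if (is.null(H) || abs(det(H)) < 1e-12) {
    stopf("degenerate consensus set: least-squares homography is singular")
  }
  err <- reprojection_errors(H, src, dst)
  inl <- which(err <= reproj_threshold)
  structure(list(H = H, inliers = inl, residual = mean(err[inl]),
                 n_pairs = n),
            class = "homography_estimate")
}

#' @export
print.homography_estimate <- function(x, ...) {
  cat(sprintf("<homography_estimate> %d/%d inliers, mean residual %.3f px\n",
              length(x$inliers), x$n_pairs, x$residual))
  print(round(x$H, 5))
  invisible(x)
}

# --- SSIM -----------------------------------------------------------------

#' Structural similarity index
#'
#' Mean local SSIM between two grayscale images with a Gaussian window
#' (default 7x7, sigma 1.5) and the standard stabilizing constants
#' `C1 = (0.01 L)^2`, `C2 = (0.03 L)^2`, `L = 255`.
#'
#' @param a,b grayscale matrices (0--255), equal dimensions, at least the
#'   window size.
#' @param window odd window width in px.
#' @return scalar in [-1, 1].
#' @export
ssim <- function(a, b, window = 7) {
  if (!all(dim(a) == dim(b))) stopf("ssim: image dimensions differ")
  if (min(dim(a)) < window) stopf("ssim: images smaller than the window")
  sigma <- 1.5
  r <- (window - 1) %/% 2
  gf <- function(m) gaussian_blur(m, sigma, radius = r)
  C1 <- (0.01 * 255)^2
  C2 <- (0.03 * 255)^2
  mu_a <- gf(a); mu_b <- gf(b)
  va <- gf(a * a) - mu_a^2
  vb <- gf(b * b) - mu_b^2
  vab <- gf(a * b) - mu_a * mu_b
  smap <- ((2 * mu_a * mu_b + C1) * (2 * vab + C2)) /
    ((mu_a^2 + mu_b^2 + C1) * (va + vb + C2))
  mean(smap)
}

# --- warping --------------------------------------------------------------

#' Warp a thermal frame with a homography
#'
#' Maps the frame into the destination (colour-harmonized) raster using the
#' inverse of `H` (which maps thermal to colour pixels): the pseudo-colour
#' image is interpolated bilinearly, the temperature grid with
#' nearest-neighbour so 0.1 degC quantization is preserved. Destination
#' pixels whose preimage falls outside the source are invalid (temperature
#' `NA`, colour 0).
#'
#' @param frame a [thermal_frame()].
#' @param H 3x3 homography mapping thermal pixels to destination pixels.
#' @param out_size `c(width, height)` of the destination raster (defaults
#'   to the frame's own size).
#' @return a `thermal_frame` in the destination raster.
#' @export
warp_thermal <- function(frame, H, out_size = NULL) {
  stopifnot(inherits(frame, "thermal_frame"))
  if (abs(det(H)) < 1e-12) stopf("warp_thermal: singular homography")
  d <- dim(frame$temperature)
  if (is.null(out_size)) out_size <- c(d[2], d[1])
  w <- out_size[1]; h <- out_size[2]
  Hi <- solve(H)
  xg <- rep(0:(w - 1), each = h)
  yg <- rep(0:(h - 1), times = w)
  s <- apply_homography(Hi, cbind(xg, yg))
  temp <- matrix(nearest_sample(frame$temperature, s[, 1], s[, 2]), h, w)
  pc <- array(0, dim = c(h, w, 3L))
  for (c in 1:3) {
    v <- bilinear_sample(frame$pseudo_color[, , c], s[, 1], s[, 2])
    v[!is.finite(v)] <- 0
    pc[, , c] <- matrix(v, h, w)
  }
  thermal_frame(pc, temp, frame$timestamp)
}

warp_gray <- function(gray, H, out_size) {
  Hi <- solve(H)
  w <- out_size[1]; h <- out_size[2]
  xg <- rep(0:(w - 1), each = h)
  yg <- rep(0:(h - 1), times = w)
  s <- apply_homography(Hi, cbind(xg, yg))
  matrix(bilinear_sample(gray, s[, 1], s[, 2]), h, w)
}

# --- coarse + fine registration -------------------------------------------

#' Coarse thermal-to-colour registration
#'
#' The photogrammetric chain: rectify the stereo pair, harmonize both
#' colour views to the thermal geometry (bicubic resize + crop derived from
#' the calibration), Laplacian-sharpen, extract the green canopy mask,
#' detect and match features under the ratio test, filter with the epipolar
#' constraint, triangulate the survivors, back-project them into the
#' thermal image, and fit the thermal-to-colour homography by RANSAC
#' (direction: thermal pixel -> harmonized colour pixel).
#'
#' @param thermal a [thermal_frame()].
#' @param pair a [color_stereo_pair()].
#' @param calib a [rig_calibration()].
#' @param config a `pipeline_config`.
#' @param illumination_klx measured illumination (used when
#'   `config$sun$mode == "auto"`).
#' @return a `homography_estimate` with extras: `stage_counts`,
#'   `keypoints` (inlier colour keypoints, harmonized frame),
#'   `projected_thermal` (their back-projections), `harmonization`.
#' @export
coarse_register <- function(thermal, pair, calib, config = default_config(),
                            illumination_klx = NULL) {
  rect <- rectify_pair(pair, calib)
  harm <- harmonization_from_calib(rect$intrinsics_left, calib$cameras$thermal)
  left_h <- harmonize_image(rect$pair$left, harm)
  right_h <- harmonize_image(rect$pair$right, harm)
  left_s <- sharpen_laplacian(left_h)
  right_s <- sharpen_laplacian(right_h)
  SL <- if (identical(config$sun$mode, "auto") && is.null(illumination_klx)) {
    config$hsv$SL_shade
  } else {
    select_saturation_lower(illumination_klx, config$sun$mode, config)
  }
  thr <- segmentation_thresholds(config$hsv$HL, config$hsv$HU, SL,
                                 config$hsv$SU, config$hsv$VL, config$hsv$VU)
  mask_l <- canopy_mask_hsv(left_h, thr)
  mask_r <- canopy_mask_hsv(right_h, thr)
  counts <- list(mask_left_px = sum(mask_l), mask_right_px = sum(mask_r))
  if (sum(mask_l) == 0 || sum(mask_r) == 0) {
    stopf("coarse registration failed: empty canopy mask (left %d px, right %d px)",
          sum(mask_l), sum(mask_r))
  }
  matches <- detect_and_match_features(apply_mask(left_s, mask_l),
                                       apply_mask(right_s, mask_r),
                                       config$matching$ratio_threshold,
                                       config$matching$max_keypoints)
  counts$matched <- nrow(matches)
  matches <- filter_epipolar(matches, config$matching$epipolar_row_tol)
  counts$epipolar <- nrow(matches)
  if (nrow(matches) < 4) {
    stopf("coarse registration failed: %d matches after epipolar filtering (stages: matched %d)",
          nrow(matches), counts$matched)
  }
  # harmonized frame intrinsics: focal and principal point of the thermal
  # camera, baseline unchanged
  tc <- calib$cameras$thermal
  wp <- triangulate_matches(matches, list(f = tc$f, cx = tc$cx, cy = tc$cy,
                                          baseline = calib$baseline_mm))
  counts$triangulated <- nrow(wp)
  kept <- attr(wp, "kept")
  # thermal pose relative to the rectified-left frame
  R_th <- calib$left_to_thermal$R %*% t(rect$R_rect_left)
  pix <- backproject_to_thermal(wp, list(K = intrinsic_matrix(tc),
                                         R = R_th, T = calib$left_to_thermal$T))
  counts$backprojected <- nrow(pix)
  kept <- kept[attr(pix, "kept")]
  if (nrow(pix) < 4) {
    stopf("coarse registration failed: %d back-projected points", nrow(pix))
  }
  dst <- cbind(matches$xl[kept], matches$yl[kept])
  est <- estimate_homography_ransac(pix, dst,
                                    config$ransac$reproj_threshold,
                                    config$ransac$seed,
                                    config$ransac$max_iter,
                                    config$ransac$confidence)
  est$stage_counts <- counts
  est$keypoints <- dst
  est$projected_thermal <- unclass(pix)[, 1:2, drop = FALSE]
  est$harmonization <- harm
  est$direction <- "thermal->color"
  est
}

#' SSIM-maximizing fine registration
#'
#' Scans integer offsets `(dx, dy)` over a square grid; for each offset the
#' back-projected thermal points are shifted by the offset, the homography
#' is re-estimated by RANSAC, the thermal image is warped into the colour
#' raster, both images are cropped to the bounding box of their co-aligned
#' (mutually valid) region, and scored with SSIM. The offset with the
#' largest SSIM wins; ties go to the smallest offset norm, then
#' lexicographic order. Offsets whose co-aligned region is empty or whose
#' RANSAC fails score -1.
#'
#' @param coarse a `homography_estimate` from [coarse_register()] (or any
#'   estimate with the same fields).
#' @param color_keypoints inlier colour keypoints, `n x 2`, harmonized
#'   frame (defaults to the coarse estimate's).
#' @param projected_thermal_points their thermal back-projections, `n x 2`.
#' @param thermal a [thermal_frame()].
#' @param color_image harmonized colour image (or grayscale matrix).
#' @param search_range maximum |dx|, |dy| in px.
#' @param step grid step in px (>= 1).
#' @param seed RANSAC seed.
#' @param reproj_threshold RANSAC inlier threshold, px.
#' @return object of class `fine_registration_result`: `delta`, `H_opt`,
#'   `ssim_score`, `ssim_coarse` (score at zero offset), `grid` (all
#'   offsets and scores).
#' @export
fine_register <- function(coarse, color_keypoints = coarse$keypoints,
                          projected_thermal_points = coarse$projected_thermal,
                          thermal, color_image, search_range = 10, step = 1,
                          seed = 1, reproj_threshold = 3) {
  stopifnot(search_range >= 0, step >= 1)
  gray_c <- to_gray(color_image)
  gray_t <- to_gray(thermal$pseudo_color)
  out_size <- c(ncol(gray_c), nrow(gray_c))
  offs <- seq(-search_range, search_range, by = step)
  grid <- expand.grid(dx = offs, dy = offs)
  grid <- grid[order(grid$dx^2 + grid$dy^2, grid$dx, grid$dy), ]
  score_one <- function(dx, dy) {
    src <- cbind(projected_thermal_points[, 1] + dx,
                 projected_thermal_points[, 2] + dy)
    H <- tryCatch(
      estimate_homography_ransac(src, color_keypoints, reproj_threshold,
                                 seed = seed)$H,
      error = function(e) NULL)
    if (is.null(H)) return(list(score = -1, H = NULL))
    wt <- warp_gray(gray_t, H, out_size)
    valid <- is.finite(wt)
    if (!any(valid)) return(list(score = -1, H = H))
    rows <- range(which(rowSums(valid) > 0))
    cols <- range(which(colSums(valid) > 0))
    if (diff(rows) + 1 < 7 || diff(cols) + 1 < 7) return(list(score = -1, H = H))
    a <- wt[rows[1]:rows[2], cols[1]:cols[2]]
    b <- gray_c[rows[1]:rows[2], cols[1]:cols[2]]
    a[!is.finite(a)] <- 0
    list(score = ssim(a, b), H = H)
  }
  best <- list(score = -Inf, H = NULL, delta = c(0, 0))
  scores <- numeric(nrow(grid))
  coarse_score <- NA_real_
  for (i in seq_len(nrow(grid))) {
    r <- score_one(grid$dx[i], grid$dy[i])
    scores[i] <- r$score
    if (grid$dx[i] == 0 && grid$dy[i] == 0) coarse_score <- r$score
    if (r$score > best$score) {
      best <- list(score = r$score, H = r$H, delta = c(grid$dx[i], grid$dy[i]))
    }
  }
  structure(list(delta = best$delta, H_opt = best$H, ssim_score = best$score,
                 ssim_coarse = coarse_score,
                 grid = cbind(grid, score = scores)),
            class = "fine_registration_result")
}

#' @export
print.fine_registration_result <- function(x, ...) {
  cat(sprintf("<fine_registration_result> delta = (%d, %d), SSIM %.4f (coarse %.4f)\n",
              x$delta[1], x$delta[2], x$ssim_score, x$ssim_coarse))
  invisible(x)
}
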