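# Fully ground-truthed synthetic greenhouse scenes: textured pseudo-leaves
# on a dominant fronto-parallel canopy plane (optionally over a deeper soil
# plane), rendered through the binocular and thermal cameras of a
# configurable rig. Planarity makes the thermal->colour homography, the
# disparity field and the temperature/CWSI fields exact closed forms, so
# every pipeline stage can be validated without real data. Photorealism is
# a non-goal; leaf texture exists so feature detectors fire.

#' Synthetic rig calibration
#'
#' Default rig: 60 mm baseline, 1280x720 colour cameras (f = 900 px),
#' 384x288 thermal camera (f = 380 px) mounted beside the left camera with
#' a small rotation, scene depths 1.2--1.5 m. `image_scale` shrinks all
#' resolutions and focal lengths together (same field of view) for fast
#' experiments.
#'
#' @param baseline_mm stereo baseline (> 0).
#' @param image_scale resolution scale factor (> 0).
#' @param color_f,thermal_f focal lengths at scale 1, px.
#' @param thermal_offset_mm thermal camera centre in the left frame, mm.
#' @param thermal_rot_deg small rotation (about x, y, z) of the thermal
#'   camera, degrees.
#' @param distortion optional 5-vector of colour-lens distortion
#'   coefficients.
#' @return a [rig_calibration()].
#' @export
make_rig <- function(baseline_mm = 60, image_scale = 1, color_f = 900,
                     thermal_f = 380, thermal_offset_mm = c(30, -20, 0),
                     thermal_rot_deg = c(0.3, 0.5, 0.2),
                     distortion = numeric(5)) {
  if (!is_scalar_number(baseline_mm) || baseline_mm <= 0) {
    stopf("baseline_mm must be > 0")
  }
  if (!is_scalar_number(image_scale) || image_scale <= 0) {
    stopf("image_scale must be > 0")
  }
  s <- image_scale
  cam <- function(w, h, f) {
    w <- round(w * s); h <- round(h * s)
    list(f = f * s, cx = (w - 1) / 2, cy = (h - 1) / 2,
         width = w, height = h, dist = as.numeric(distortion))
  }
  R_th <- rotation_xyz(thermal_rot_deg * pi / 180)
  rig_calibration(
    cameras = list(left = cam(1280, 720, color_f),
                   right = cam(1280, 720, color_f),
                   thermal = cam(384, 288, thermal_f)),
    left_to_right = list(R = diag(3), T = c(-baseline_mm, 0, 0)),
    left_to_thermal = list(R = R_th,
                           T = as.numeric(-R_th %*% thermal_offset_mm)),
    baseline_mm = baseline_mm)
}

rotation_xyz <- function(ang) {
  cx <- cos(ang[1]); sx <- sin(ang[1])
  cy <- cos(ang[2]); sy <- sin(ang[2])
  cz <- cos(ang[3]); sz <- sin(ang[3])
  Rx <- matrix(c(1, 0, 0, 0, cx, -sx, 0, sx, cx), 3, 3, byrow = TRUE)
  Ry <- matrix(c(cy, 0, sy, 0, 1, 0, -sy, 0, cy), 3, 3, byrow = TRUE)
  Rz <- matrix(c(cz, -sz, 0, sz, cz, 0, 0, 0, 1), 3, 3, byrow = TRUE)
  Rz %*% Ry %*% Rx
}

# Smooth value noise over plane coordinates (mm): a seeded random lattice
# interpolated with smoothstep weights; deterministic given the RNG state.
make_value_noise <- function(extent, cell_mm) {
  gw <- max(2L, ceiling(diff(extent$u) / cell_mm) + 2L)
  gh <- max(2L, ceiling(diff(extent$v) / cell_mm) + 2L)
  G <- matrix(runif(gw * gh), gh, gw)
  function(u, v) {
    gu <- (u - extent$u[1]) / cell_mm + 1
    gv <- (v - extent$v[1]) / cell_mm + 1
    gu <- pmin(pmax(gu, 1), gw - 1e-9)
    gv <- pmin(pmax(gv, 1), gh - 1e-9)
    u0 <- floor(gu); v0 <- floor(gv)
    fu <- gu - u0; fv <- gv - v0
    fu <- fu * fu * (3 - 2 * fu)
    fv <- fv * fv * (3 - 2 * fv)
    i00 <- (u0 - 1) * gh + v0
    (1 - fu) * (1 - fv) * G[i00] + fu * (1 - fv) * G[i00 + gh] +
      (1 - fu) * fv * G[i00 + 1] + fu * fv * G[i00 + gh + 1]
  }
}

hsv180_to_rgb <- function(h, s, v) {
  # h on 0-180, s,v on 0-255 -> r,g,b on 0-255
  h6 <- (h / 180) * 6
  s1 <- s / 255; v1 <- v / 255
  i <- floor(h6) %% 6
  f <- h6 - floor(h6)
  p <- v1 * (1 - s1)
  q <- v1 * (1 - f * s1)
  t <- v1 * (1 - (1 - f) * s1)
  r <- ifelse(i == 0, v1, ifelse(i == 1, q, ifelse(i == 2, p,
        ifelse(i == 3, p, ifelse(i == 4, t, v1)))))
  g <- ifelse(i == 0, t, ifelse(i == 1, v1, ifelse(i == 2, v1,
        ifelse(i == 3, q, ifelse(i == 4, p, p)))))
  b <- ifelse(i == 0, p, ifelse(i == 1, p, ifelse(i == 2, t,
        ifelse(i == 3, v1, ifelse(i == 4, v1, q)))))
  list(r = r * 255, g = g * 255, b = b * 255)
}

#' Render a ground-truthed synthetic canopy scene
#'
#' Textured elliptical pseudo-leaves (hues inside the canopy band 35--100
#' on the 0--180 scale) on a fronto-parallel canopy plane over a
#' soil-coloured background, rendered through the rig's three cameras. The
#' temperature field on the canopy is planted through an explicit CWSI
#' field (`T = T_wet + CWSI * (T_dry - T_wet)`), soil is hotter; the
#' measured thermal grid adds Gaussian noise and 0.1 degC quantization.
#' Optional planted hot-edge artefacts (leaf-boundary pixels carrying
#' soil-like temperature, as misregistration produces) and a per-leaf
#' jitter between the colour and thermal renders (leaf motion between
#' exposures). Everything is a pure function of `(seed, parameters)`.
#'
#' @param rig a [rig_calibration()], e.g. [make_rig()].
#' @param seed integer seed.
#' @param n_leaves number of leaves.
#' @param depth_range canopy-plane depth range, mm; the plane depth is
#'   drawn uniformly inside it.
#' @param two_plane render soil on a second, deeper plane
#'   (`soil_depth_offset` mm behind the canopy) instead of the canopy
#'   plane.
#' @param soil_depth_offset soil plane offset, mm.
#' @param temp temperature parameters: `T_air`, `T_wet`, `dry_offset`,
#'   `cwsi_base`, `cwsi_amp` (planted CWSI = base + amp * smooth noise),
#'   `noise_sd` (degC), `soil_offset` (soil = T_air + offset).
#' @param artifact_edge_px width (thermal px) of the planted hot-edge band
#'   around leaf boundaries; 0 disables.
#' @param artifact_temp_gap artefact temperature = mean canopy temperature
#'   + this gap (degC).
#' @param leaf_jitter_mm per-leaf random displacement between colour and
#'   thermal renders.
#' @param landmark_click_sd marking noise (px) added to the leaf-centre
#'   landmarks in each view, emulating operator control-point selection;
#'   the exact projections are kept in `truth$landmarks_true`.
#' @param illumination_klx environment record illumination.
#' @param timestamp ISO-8601 acquisition time.
#' @return object of class `canopy_scene`: `pair` (a
#'   [color_stereo_pair()]), `thermal` (a [thermal_frame()]), `env`
#'   (one-row data frame), `rig`, and `truth` (class `scene_truth`:
#'   `H_thermal_to_color` for the harmonized colour raster, per-pixel
#'   `disparity` on the left raster, `temperature`, `cwsi` and `labels`
#'   on the thermal raster, `refs`, `landmarks`, `harmonization`, `seed`).
#' @export
render_canopy_scene <- function(rig = make_rig(), seed = 1, n_leaves = 110,
                                depth_range = c(1200, 1500),
                                two_plane = FALSE, soil_depth_offset = 150,
                                temp = list(), artifact_edge_px = 0,
                                artifact_temp_gap = 10, leaf_jitter_mm = 0,
                                landmark_click_sd = 0.5,
                                illumination_klx = 70,
                                timestamp = "2022-04-26T11:30:00") {
  if (any(depth_range <= 0)) stopf("depth_range must be positive")
  tp <- modify_list_deep(list(T_air = 29.5, T_wet = 21, dry_offset = 7,
                              cwsi_base = 0.35, cwsi_amp = 0.15,
                              noise_sd = 0.1, soil_offset = 6), temp)
  refs <- reference_temperatures(tp$T_wet, tp$T_air, tp$dry_offset)
  with_seed(seed, {
    Z0 <- runif(1, depth_range[1], depth_range[2])
    Zsoil <- if (two_plane) Z0 + soil_depth_offset else Z0
    cl <- rig$cameras$left
    half_u <- (cl$width / 2) / cl$f * Zsoil * 1.25 + 2 * rig$baseline_mm
    half_v <- (cl$height / 2) / cl$f * Zsoil * 1.25 + 50
    extent <- list(u = c(-half_u, half_u), v = c(-half_v, half_v))

    leaves <- data.frame(
      u = runif(n_leaves, -0.85 * half_u, 0.85 * half_u),
      v = runif(n_leaves, -0.85 * half_v, 0.85 * half_v),
      a = runif(n_leaves, 45, 95), b = runif(n_leaves, 28, 60),
      th = runif(n_leaves, 0, pi),
      hue = runif(n_leaves, 45, 90),      # green band on the 0-180 scale
      sat = runif(n_leaves, 140, 220),
      val = runif(n_leaves, 120, 210),
      ju = rnorm(n_leaves, 0, max(leaf_jitter_mm, 1e-9)),
      jv = rnorm(n_leaves, 0, max(leaf_jitter_mm, 1e-9)))
    if (leaf_jitter_mm == 0) {
      leaves$ju <- rep(0, n_leaves)
      leaves$jv <- rep(0, n_leaves)
    }

    vn_tex <- make_value_noise(extent, cell_mm = 12)
    vn_fine <- make_value_noise(extent, cell_mm = 4)
    vn_cwsi <- make_value_noise(extent, cell_mm = 120)
    vn_soil <- make_value_noise(extent, cell_mm = 25)

    leaf_id_at <- function(u, v, jitter = FALSE) {
      id <- integer(length(u))
      for (i in seq_len(nrow(leaves))) {
        du <- u - leaves$u[i] - if (jitter) leaves$ju[i] else 0
        dv <- v - leaves$v[i] - if (jitter) leaves$jv[i] else 0
        ct <- cos(leaves$th[i]); st <- sin(leaves$th[i])
        e <- ((du * ct + dv * st) / leaves$a[i])^2 +
          ((-du * st + dv * ct) / leaves$b[i])^2
        id[e <= 1] <- i
      }
      id
    }
    cwsi_at <- function(u, v) {
      pmin(pmax(tp$cwsi_base + tp$cwsi_amp * (2 * vn_cwsi(u, v) - 1), 0), 1)
    }
    temp_at <- function(u, v, id) {
      tc <- refs$T_wet + cwsi_at(u, v) * (refs$T_dry - refs$T_wet)
      ts <- refs$T_air + tp$soil_offset + 1.5 * (vn_soil(u, v) - 0.5)
      ifelse(id > 0, tc, ts)
    }
    color_at <- function(u, v, id) {
      n <- length(u)
      tex <- vn_tex(u, v); fine <- vn_fine(u, v)
      hue <- ifelse(id > 0, leaves$hue[pmax(id, 1)] + 8 * (tex - 0.5), 12 + 8 * tex)
      sat <- ifelse(id > 0, leaves$sat[pmax(id, 1)] + 50 * (fine - 0.5), 90 + 40 * fine)
      val <- ifelse(id > 0, leaves$val[pmax(id, 1)] + 70 * (fine - 0.5), 80 + 60 * tex)
      hsv180_to_rgb(pmin(pmax(hue, 0), 179.9), pmin(pmax(sat, 0), 255),
                    pmin(pmax(val, 10), 255))
    }

    # pixel -> plane coordinates for a camera at pose (R, T) rel. left
    pix_to_plane <- function(cam, R, T, Zp) {
      w <- cam$width; h <- cam$height
      xg <- rep(0:(w - 1), each = h)
      yg <- rep(0:(h - 1), times = w)
      C <- -as.numeric(t(R) %*% T)
      dir <- t(R) %*% rbind((xg - cam$cx) / cam$f, (yg - cam$cy) / cam$f, 1)
      tt <- (Zp - C[3]) / dir[3, ]
      list(u = C[1] + tt * dir[1, ], v = C[2] + tt * dir[2, ],
           w = w, h = h)
    }
    render_color <- function(cam, R, T) {
      pc <- pix_to_plane(cam, R, T, Z0)
      id <- leaf_id_at(pc$u, pc$v)
      if (two_plane) {
        ps <- pix_to_plane(cam, R, T, Zsoil)
        u <- ifelse(id > 0, pc$u, ps$u)
        v <- ifelse(id > 0, pc$v, ps$v)
      } else { u <- pc$u; v <- pc$v }
      col <- color_at(u, v, id)
      img <- array(0, dim = c(pc$h, pc$w, 3L))
      img[, , 1] <- matrix(col$r, pc$h, pc$w)
      img[, , 2] <- matrix(col$g, pc$h, pc$w)
      img[, , 3] <- matrix(col$b, pc$h, pc$w)
      list(img = img, id = matrix(id, pc$h, pc$w))
    }

    left <- render_color(cl, diag(3), c(0, 0, 0))
    right <- render_color(rig$cameras$right, rig$left_to_right$R,
                          rig$left_to_right$T)

    # thermal render (leaf jitter applies here)
    tc <- rig$cameras$thermal
    Rt <- rig$left_to_thermal$R; Tt <- rig$left_to_thermal$T
    pt <- pix_to_plane(tc, Rt, Tt, Z0)
    id_t <- leaf_id_at(pt$u, pt$v, jitter = TRUE)
    if (two_plane) {
      ps <- pix_to_plane(tc, Rt, Tt, Zsoil)
      ut <- ifelse(id_t > 0, pt$u, ps$u)
      vt <- ifelse(id_t > 0, pt$v, ps$v)
    } else { ut <- pt$u; vt <- pt$v }
    temp_true <- matrix(temp_at(ut, vt, id_t), pt$h, pt$w)
    cwsi_true <- matrix(ifelse(id_t > 0, cwsi_at(ut, vt), NA_real_), pt$h, pt$w)
    labels <- matrix(ifelse(id_t > 0, "canopy", "soil"), pt$h, pt$w)

    if (artifact_edge_px > 0) {
      canopy <- matrix(id_t > 0, pt$h, pt$w)
      inner <- canopy
      for (i in seq_len(artifact_edge_px)) {
        inner <- inner & shift_pad(inner, 1, 0, FALSE) &
          shift_pad(inner, -1, 0, FALSE) & shift_pad(inner, 0, 1, FALSE) &
          shift_pad(inner, 0, -1, FALSE)
      }
      edge <- canopy & !inner
      mean_canopy <- mean(temp_true[canopy])
      temp_true[edge] <- mean_canopy + artifact_temp_gap
      labels[edge] <- "artifact"
      cwsi_true[edge] <- NA_real_
    }

    temp_meas <- temp_true + rnorm(length(temp_true), 0, tp$noise_sd)
    temp_meas <- round(temp_meas, 1)    # 0.1 degC measurement resolution
    # decreasing affine map of temperature: cool canopy renders bright, hot
    # soil dark, matching the luminance ordering of the colour render
    tmin <- min(temp_meas); tmax <- max(temp_meas)
    inten <- (tmax - temp_meas) / max(tmax - tmin, 0.1) * 235 + 20
    pseudo <- array(0, dim = c(pt$h, pt$w, 3L))
    pseudo[, , 1] <- pmin(inten * 1.4, 255)
    pseudo[, , 2] <- inten * 0.75
    pseudo[, , 3] <- pmax(inten * 1.6 - 200, 0)

    thermal <- thermal_frame(pseudo, matrix(temp_meas, pt$h, pt$w), timestamp)

    # closed-form truth: plane-induced homography thermal -> harmonized left
    harm <- harmonization_from_calib(cl, tc)
    M <- diag(3); M[3, 3] <- Z0
    H_left_plane <- intrinsic_matrix(cl) %*% M
    H_th_plane <- intrinsic_matrix(tc) %*%
      cbind(Rt[, 1], Rt[, 2], Rt[, 3] * Z0 + Tt)
    A_harm <- matrix(c(harm$scale, 0, -harm$offset[1],
                       0, harm$scale, -harm$offset[2], 0, 0, 1), 3, 3,
                     byrow = TRUE)
    H_true <- A_harm %*% H_left_plane %*% solve(H_th_plane)
    H_true <- H_true / H_true[3, 3]

    disparity <- matrix(cl$f * rig$baseline_mm / Z0, cl$height, cl$width)
    if (two_plane) {
      disparity[left$id == 0] <- cl$f * rig$baseline_mm / Zsoil
    }

    # landmarks: leaf centres visible in both the harmonized colour and
    # thermal rasters
    lm_w <- cbind(leaves$u, leaves$v, rep(Z0, n_leaves))
    proj <- function(K, R, T) {
      if (!nrow(lm_w)) return(matrix(numeric(), 0, 2))
      p <- K %*% (R %*% t(lm_w) + T)
      cbind(p[1, ] / p[3, ], p[2, ] / p[3, ])
    }
    lm_l <- proj(intrinsic_matrix(cl), diag(3), c(0, 0, 0))
    lm_h <- if (nrow(lm_l)) harmonize_points(lm_l, harm) else lm_l
    lm_t <- proj(intrinsic_matrix(tc), Rt, Tt)
    vis <- lm_h[, 1] >= 0 & lm_h[, 1] <= tc$width - 1 &
      lm_h[, 2] >= 0 & lm_h[, 2] <= tc$height - 1 &
      lm_t[, 1] >= 0 & lm_t[, 1] <= tc$width - 1 &
      lm_t[, 2] >= 0 & lm_t[, 2] <= tc$height - 1
    # "clicked" landmarks: the exact projections plus independent marking
    # noise in each view, emulating operator control-point selection
    lm_h_click <- lm_h + matrix(rnorm(2 * nrow(lm_h), 0, landmark_click_sd),
                                ncol = 2)
    lm_t_click <- lm_t + matrix(rnorm(2 * nrow(lm_t), 0, landmark_click_sd),
                                ncol = 2)

    truth <- structure(list(
      H_thermal_to_color = H_true, disparity = disparity,
      temperature = matrix(temp_true, pt$h, pt$w), cwsi = cwsi_true,
      labels = labels, labels_left = ifelse(left$id > 0, "canopy", "soil"),
      refs = refs, plane_depth = Z0, soil_depth = Zsoil,
      harmonization = harm,
      landmarks = list(color = lm_h_click[vis, , drop = FALSE],
                       thermal = lm_t_click[vis, , drop = FALSE]),
      landmarks_true = list(color = lm_h[vis, , drop = FALSE],
                            thermal = lm_t[vis, , drop = FALSE]),
      seed = seed), class = "scene_truth")

    structure(list(
      pair = color_stereo_pair(left$img, right$img, timestamp),
      thermal = thermal, rig = rig,
      env = data.frame(time = timestamp, t_air = tp$T_air,
                       illumination_klx = illumination_klx),
      truth = truth), class = "canopy_scene")
  })
}

#' @export
print.canopy_scene <- function(x, ...) {
  cat(sprintf("<canopy_scene> seed %s, canopy plane at %.0f mm, %d%% canopy px\n",
              format(x$truth$seed), x$truth$plane_depth,
              round(100 * mean(x$truth$labels == "canopy"))))
  invisible(x)
}

#' Point cloud from scene ground truth
#'
#' Builds a fused point cloud directly from the scene's thermal-raster
#' ground truth (plane geometry, measured temperatures, rendered pseudo
#' colours mapped to leaf/soil RGB), with the per-point truth label in
#' `attr(, "labels")`. Used to validate the cleaning stages against known
#' labels.
#'
#' @param scene a `canopy_scene`.
#' @return a [fused_point_cloud()] with `attr(, "labels")` and
#'   `attr(, "cwsi_true")`.
#' @export
scene_truth_cloud <- function(scene) {
  tr <- scene$truth
  tc <- scene$rig$cameras$thermal
  Rt <- scene$rig$left_to_thermal$R; Tt <- scene$rig$left_to_thermal$T
  h <- nrow(tr$temperature); w <- ncol(tr$temperature)
  xg <- rep(0:(w - 1), each = h)
  yg <- rep(0:(h - 1), times = w)
  C <- -as.numeric(t(Rt) %*% Tt)
  dir <- t(Rt) %*% rbind((xg - tc$cx) / tc$f, (yg - tc$cy) / tc$f, 1)
  tt <- (tr$plane_depth - C[3]) / dir[3, ]
  X <- C[1] + tt * dir[1, ]; Y <- C[2] + tt * dir[2, ]
  lab <- as.vector(tr$labels)
  canopy <- lab != "soil"
  # leaf-green vs soil-brown colours so the HSV filter sees realistic input
  col <- ifelse(canopy, 1, 0)
  rgb <- hsv180_to_rgb(ifelse(canopy, 65, 12), ifelse(canopy, 180, 110),
                       ifelse(canopy, 170, 110))
  cloud <- fused_point_cloud(
    x = X, y = Y, z = rep(tr$plane_depth, length(X)),
    r = rgb$r, g = rgb$g, b = rgb$b,
    temperature = as.vector(scene$thermal$temperature))
  attr(cloud, "labels") <- lab
  attr(cloud, "cwsi_true") <- as.vector(tr$cwsi)
  cloud
}

#' Checkerboard calibration fixture
#'
#' Renders a planar checkerboard (default 30 mm squares) through the left
#' colour and thermal cameras and returns the inner-corner ground truth:
#' world coordinates and per-view pixel projections. Deterministic (no
#' randomness).
#'
#' @param square_mm square side, mm.
#' @param layout `c(rows, cols)` of squares, each >= 3.
#' @param depth plane depth, mm.
#' @param rig a [rig_calibration()].
#' @return list: `color`, `thermal` (rendered images), `corners_world`
#'   (`n x 3` mm), `corners_color`, `corners_thermal` (`n x 2` px).
#' @export
make_checkerboard_fixture <- function(square_mm = 30, layout = c(7, 9),
                                      depth = 1350, rig = make_rig()) {
  if (any(layout < 3)) stopf("checkerboard layout must be at least 3x3 squares")
  rows <- layout[1]; cols <- layout[2]
  half_w <- cols * square_mm / 2
  half_h <- rows * square_mm / 2
  checker_at <- function(u, v) {
    iu <- floor((u + half_w) / square_mm)
    iv <- floor((v + half_h) / square_mm)
    inside <- u >= -half_w & u < half_w & v >= -half_h & v < half_h
    ifelse(inside, ifelse((iu + iv) %% 2 == 0, 250, 15), 128)
  }
  render <- function(cam, R, T) {
    w <- cam$width; h <- cam$height
    xg <- rep(0:(w - 1), each = h)
    yg <- rep(0:(h - 1), times = w)
    C <- -as.numeric(t(R) %*% T)
    dir <- t(R) %*% rbind((xg - cam$cx) / cam$f, (yg - cam$cy) / cam$f, 1)
    tt <- (depth - C[3]) / dir[3, ]
    g <- matrix(checker_at(C[1] + tt * dir[1, ], C[2] + tt * dir[2, ]), h, w)
    array(rep(g, 3), dim = c(h, w, 3L))
  }
  cw <- expand.grid(u = (seq_len(cols - 1) - cols / 2) * square_mm,
                    v = (seq_len(rows - 1) - rows / 2) * square_mm)
  corners_world <- cbind(cw$u, cw$v, depth)
  proj <- function(K, R, T) {
    p <- K %*% (R %*% t(corners_world) + T)
    cbind(p[1, ] / p[3, ], p[2, ] / p[3, ])
  }
  list(color = render(rig$cameras$left, diag(3), c(0, 0, 0)),
       thermal = render(rig$cameras$thermal, rig$left_to_thermal$R,
                        rig$left_to_thermal$T),
       corners_world = corners_world,
       corners_color = proj(intrinsic_matrix(rig$cameras$left), diag(3),
                            c(0, 0, 0)),
       corners_thermal = proj(intrinsic_matrix(rig$cameras$thermal),
                              rig$left_to_thermal$R, rig$left_to_thermal$T))
}
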