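#' Run the full 3D CWSI pipeline
#'
#' Chains the stages end to end on in-memory inputs: coarse + fine
#' thermal-to-colour registration, thermal warp, stereo rectification,
#' SGBM disparity with median filtering and multi-level mean hole filling,
#' depth and 3D reprojection, fusion into an XYZ+RGB+temperature cloud,
#' the three-step cleaning chain, and per-point CWSI against the wet/dry
#' references.
#'
#' @param thermal a [thermal_frame()].
#' @param pair a [color_stereo_pair()].
#' @param calib a [rig_calibration()].
#' @param config a `pipeline_config`.
#' @param T_air air temperature, degC.
#' @param T_wet wet-reference temperature, degC; alternatively supply
#'   `wet_roi` (pixel box on the warped temperature grid) to measure it.
#' @param wet_roi optional `c(x0, y0, x1, y1)` pixel box.
#' @param illumination_klx optional illumination for the sun-mode rule.
#' @return list: `coarse`, `fine`, `warped` (warped `thermal_frame`),
#'   `disparity`, `depth`, `cloud` (cleaned, with CWSI), `report`
#'   (cleaning report), `refs`, `summary` (one-row data frame).
#' @export
run_pipeline <- function(thermal, pair, calib, config = default_config(),
                         T_air, T_wet = NULL, wet_roi = config$cwsi$wet_roi,
                         illumination_klx = NULL) {
  coarse <- coarse_register(thermal, pair, calib, config, illumination_klx)
  fine <- fine_register(coarse, thermal = thermal,
                        color_image = harmonize_image(pair$left,
                                                      coarse$harmonization),
                        search_range = config$fine$search_range,
                        step = config$fine$step,
                        seed = config$ransac$seed,
                        reproj_threshold = config$ransac$reproj_threshold)
  warped <- warp_thermal(thermal, fine$H_opt)

  rect <- rectify_pair(pair, calib)
  sp <- config$stereo
  if (is.null(sp$min_disparity) || is.null(sp$num_disparities)) {
    sp <- stereo_params_for_rig(calib, params = sp)
  }
  disp <- compute_disparity(rect$pair, sp)
  disp <- median_filter_disparity(disp, config$disparity$median_window)
  disp <- multilevel_mean_fill(disp, config$disparity$fill_initial_window)
  depth <- disparity_to_depth(disp, rect$intrinsics$baseline,
                              rect$intrinsics$f)
  pts <- reproject_to_3d(depth, rect$intrinsics)

  temp_full <- temperature_on_color_raster(warped$temperature,
                                           coarse$harmonization,
                                           dim(depth))
  cloud <- fuse(pts, rect$pair$left, temp_full)
  SL <- if (is.null(illumination_klx) && identical(config$sun$mode, "auto")) {
    config$hsv$SL_shade
  } else {
    select_saturation_lower(illumination_klx, config$sun$mode, config)
  }
  thr <- segmentation_thresholds(config$hsv$HL, config$hsv$HU, SL,
                                 config$hsv$SU, config$hsv$VL, config$hsv$VU)
  cleaned <- clean_point_cloud(cloud, thr, config)

  if (is.null(T_wet)) {
    if (is.null(wet_roi)) stopf("run_pipeline: supply T_wet or wet_roi")
    T_wet <- wet_reference_from_roi(warped$temperature, wet_roi)
  }
  refs <- reference_temperatures(T_wet, T_air, config$cwsi$dry_offset)
  field <- compute_cwsi_field(cleaned$cloud, refs)
  summary <- canopy_mean_cwsi(field, thermal$timestamp, T_air,
                              illumination_klx %||% NA_real_)
  list(coarse = coarse, fine = fine, warped = warped, disparity = disp,
       depth = depth, cloud = field, report = cleaned$report, refs = refs,
       summary = summary)
}
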