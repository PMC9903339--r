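#' Segmentation thresholds
#'
#' HSV bounds for green-canopy extraction: hue on the 0--180 half-degree
#' scale, saturation and value on 0--255. A pixel is canopy iff all three
#' channels fall inside their `[lower, upper]` interval.
#'
#' @param HL,HU hue bounds (0--180), `HL < HU`.
#' @param SL,SU saturation bounds (0--255).
#' @param VL,VU value bounds (0--255).
#' @export
segmentation_thresholds <- function(HL = 35, HU = 100, SL = 35, SU = 255,
                                    VL = 0, VU = 255) {
  if (!(HL < HU)) stopf("HL must be < HU")
  if (!(SL < SU)) stopf("SL must be < SU")
  if (!(VL < VU)) stopf("VL must be < VU")
  structure(list(HL = HL, HU = HU, SL = SL, SU = SU, VL = VL, VU = VU),
            class = "segmentation_thresholds")
}

#' Harmonize a colour image to the thermal geometry
#'
#' Bicubic resize by `scale` followed by a crop to the thermal resolution,
#' so the colour and thermal rasters share pixel pitch and extent. With the
#' default `out_size = c(384, 288)` the output matches the thermal camera.
#'
#' @param color `h x w x 3` image (0--255).
#' @param scale resize ratio applied to both axes.
#' @param crop_origin 0-based `(x, y)` top-left corner of the crop window in
#'   the resized image.
#' @param out_size `c(width, height)` of the output.
#' @return colour array `out_size[2] x out_size[1] x 3`.
#' @export
harmonize_color_to_thermal <- function(color, scale, crop_origin = c(0, 0),
                                       out_size = c(384, 288)) {
  stopifnot(length(dim(color)) == 3L, scale > 0)
  h <- dim(color)[1]; w <- dim(color)[2]
  sw <- max(1L, round(w * scale)); sh <- max(1L, round(h * scale))
  if (crop_origin[1] < 0 || crop_origin[2] < 0 ||
      crop_origin[1] + out_size[1] > sw || crop_origin[2] + out_size[2] > sh) {
    stopf("crop window %dx%d at (%g,%g) exceeds scaled image %dx%d",
          out_size[1], out_size[2], crop_origin[1], crop_origin[2], sw, sh)
  }
  scaled <- if (sw == w && sh == h) color else resize_bicubic(color, sw, sh)
  crop_image(scaled, round(crop_origin[1]), round(crop_origin[2]),
             out_size[1], out_size[2])
}

# Harmonization parameters derived from calibration: the scale equates the
# focal lengths (thermal / colour) and the crop centres the thermal
# principal point on the colour one. Returns the affine colour->harmonized
# pixel map x' = s*x - ox, y' = s*y - oy.
harmonization_from_calib <- function(color_cam, thermal_cam) {
  s <- thermal_cam$f / color_cam$f
  ox <- s * color_cam$cx - thermal_cam$cx
  oy <- s * color_cam$cy - thermal_cam$cy
  list(scale = s, offset = c(ox, oy),
       out_size = c(thermal_cam$width, thermal_cam$height))
}

harmonize_points <- function(xy, harm) {
  cbind(harm$scale * xy[, 1] - harm$offset[1],
        harm$scale * xy[, 2] - harm$offset[2])
}

# Applies harmonization to an image: bicubic sampling of the colour image at
# the preimage of each harmonized pixel (equivalent to resize+crop but exact
# for non-integer crop origins).
harmonize_image <- function(color, harm) {
  w <- harm$out_size[1]; h <- harm$out_size[2]
  xg <- rep(0:(w - 1), each = h)
  yg <- rep(0:(h - 1), times = w)
  sx <- (xg + harm$offset[1]) / harm$scale
  sy <- (yg + harm$offset[2]) / harm$scale
  sample_one <- function(mat) {
    v <- bicubic_sample(mat, pmin(pmax(sx, 0), ncol(mat) - 1),
                        pmin(pmax(sy, 0), nrow(mat) - 1))
    matrix(clamp255(v), h, w)
  }
  if (is.matrix(color)) return(sample_one(color))
  out <- array(0, dim = c(h, w, 3L))
  for (c in 1:3) out[, , c] <- sample_one(color[, , c])
  out
}

#' Laplacian sharpening
#'
#' Unsharp enhancement `output = input - Laplacian(input)` per channel with
#' the 4-neighbour kernel `[[0,1,0],[1,-4,1],[0,1,0]]` and replicate edge
#' padding, clipped to 0--255. A constant image is unchanged.
#'
#' @param image colour array or grayscale matrix (0--255).
#' @export
sharpen_laplacian <- function(image) {
  lap <- matrix(c(0, 1, 0, 1, -4, 1, 0, 1, 0), 3, 3, byrow = TRUE)
  sharp_one <- function(mat) clamp255(mat - convolve2d_replicate(mat, lap))
  if (is.matrix(image)) return(sharp_one(image))
  stopifnot(length(dim(image)) == 3L)
  out <- image
  for (c in 1:3) out[, , c] <- sharp_one(image[, , c])
  out
}

#' Green-canopy mask in HSV space
#'
#' Converts RGB to HSV and returns the conjunction of the three channel
#' interval tests: mask is 1 iff `HL <= H <= HU` and `SL <= S <= SU` and
#' `VL <= V <= VU`.
#'
#' @param image colour array (0--255).
#' @param thresholds a [segmentation_thresholds()].
#' @return binary matrix (0/1) of the image dimensions.
#' @export
canopy_mask_hsv <- function(image, thresholds = segmentation_thresholds()) {
  stopifnot(length(dim(image)) == 3L)
  t <- thresholds
  hsv <- rgb_to_hsv180(image[, , 1], image[, , 2], image[, , 3])
  m <- (hsv$h >= t$HL & hsv$h <= t$HU &
          hsv$s >= t$SL & hsv$s <= t$SU &
          hsv$v >= t$VL & hsv$v <= t$VU)
  matrix(as.numeric(m), dim(image)[1], dim(image)[2])
}

#' Select the lower saturation bound from the illumination regime
#'
#' Under direct sun the canopy's saturation drops, so the lower saturation
#' bound is 35; in shade / diffuse light it is 60. The regime is given
#' explicitly (`mode`) or inferred by comparing the illumination (klx)
#' against the configured threshold (default 50 klx).
#'
#' @param illumination_klx measured illumination in klx (optional when
#'   `mode` is given).
#' @param mode `"direct"`, `"shade"` or `"auto"`.
#' @param config a `pipeline_config`.
#' @return the SL value (35 or 60).
#' @export
select_saturation_lower <- function(illumination_klx = NULL, mode = "auto",
                                    config = default_config()) {
  if (mode == "auto") {
    if (is.null(illumination_klx) || !is.finite(illumination_klx)) {
      stopf("select_saturation_lower: need either an explicit mode or a finite illumination")
    }
    mode <- if (illumination_klx >= config$sun$illumination_threshold_klx)
      "direct" else "shade"
  }
  switch(mode,
         direct = config$hsv$SL_direct,
         shade = config$hsv$SL_shade,
         stopf("unknown sun mode '%s'", mode))
}

#' Apply a binary mask to an image
#'
#' Pixels where the mask is 0 are set to 0; pixels where it is nonzero are
#' preserved.
#'
#' @param image colour array or grayscale matrix.
#' @param mask binary matrix of the image dimensions.
#' @export
apply_mask <- function(image, mask) {
  d <- dim(image)
  if (!all(d[1:2] == dim(mask))) stopf("image and mask dimensions differ")
  keep <- mask != 0
  if (is.matrix(image)) return(image * keep)
  out <- image
  for (c in 1:3) out[, , c] <- image[, , c] * keep
  out
}
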