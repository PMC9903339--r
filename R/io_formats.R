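#' Thermal frame
#'
#' Pairs a pseudo-colour thermal image with its per-pixel temperature grid
#' (degrees Celsius). The two rasters must have identical dimensions; the
#' thermal camera reports temperatures at 0.1 degC resolution. Invalid pixels
#' (introduced by warping) carry `NA`.
#'
#' @param pseudo_color `h x w x 3` array in 0--255.
#' @param temperature `h x w` matrix of degC values (NA = invalid).
#' @param timestamp ISO-8601 string.
#' @return object of class `thermal_frame`.
#' @export
thermal_frame <- function(pseudo_color, temperature, timestamp = NA_character_) {
  if (length(dim(pseudo_color)) != 3L) stopf("pseudo_color must be an h x w x 3 array")
  if (!is.matrix(temperature)) stopf("temperature must be a matrix")
  if (!all(dim(pseudo_color)[1:2] == dim(temperature))) {
    stopf("pseudo_color (%dx%d) and temperature (%dx%d) dimensions differ",
          dim(pseudo_color)[1], dim(pseudo_color)[2],
          nrow(temperature), ncol(temperature))
  }
  tv <- temperature[is.finite(temperature)]
  if (length(tv) && (min(tv) < -40 || max(tv) > 150)) {
    stopf("temperature values outside [-40, 150] degC")
  }
  structure(list(pseudo_color = pseudo_color, temperature = temperature,
                 timestamp = timestamp),
            class = "thermal_frame")
}

#' @export
print.thermal_frame <- function(x, ...) {
  d <- dim(x$temperature)
  tv <- x$temperature[is.finite(x$temperature)]
  cat(sprintf("<thermal_frame> %dx%d px, temperature %s degC, %d invalid px\n",
              d[2], d[1],
              if (length(tv)) sprintf("[%.1f, %.1f]", min(tv), max(tv)) else "(none)",
              sum(!is.finite(x$temperature))))
  invisible(x)
}

#' Binocular colour pair
#'
#' @param left,right `h x w x 3` arrays in 0--255, equal dimensions.
#' @param timestamp ISO-8601 string.
#' @return object of class `color_stereo_pair`.
#' @export
color_stereo_pair <- function(left, right, timestamp = NA_character_) {
  if (!all(dim(left) == dim(right))) stopf("left and right images differ in size")
  structure(list(left = left, right = right, timestamp = timestamp),
            class = "color_stereo_pair")
}

#' Fused point cloud
#'
#' A point cloud whose vertices carry 3D position (mm, left-camera frame),
#' RGB colour (0--255) and surface temperature (degC), plus an optional crop
#' water stress index in [0, 1].
#'
#' @param x,y,z coordinates in mm.
#' @param r,g,b colours in 0--255.
#' @param temperature degC per point.
#' @param cwsi optional CWSI per point.
#' @return object of class `fused_point_cloud` (a data frame).
#' @export
fused_point_cloud <- function(x = numeric(), y = numeric(), z = numeric(),
                              r = numeric(), g = numeric(), b = numeric(),
                              temperature = numeric(), cwsi = NULL) {
  n <- length(x)
  stopifnot(length(y) == n, length(z) == n, length(r) == n, length(g) == n,
            length(b) == n, length(temperature) == n)
  if (n && !all(is.finite(x) & is.finite(y) & is.finite(z))) {
    stopf("point coordinates must be finite")
  }
  if (n && (min(temperature) < -40 || max(temperature) > 150)) {
    stopf("temperatures outside [-40, 150] degC")
  }
  df <- data.frame(x = as.numeric(x), y = as.numeric(y), z = as.numeric(z),
                   r = as.numeric(r), g = as.numeric(g), b = as.numeric(b),
                   temperature = as.numeric(temperature))
  if (!is.null(cwsi)) {
    stopifnot(length(cwsi) == n)
    if (n && (min(cwsi) < 0 || max(cwsi) > 1)) stopf("cwsi outside [0, 1]")
    df$cwsi <- as.numeric(cwsi)
  }
  class(df) <- c("fused_point_cloud", "data.frame")
  df
}

#' @export
print.fused_point_cloud <- function(x, ...) {
  cat(sprintf("<fused_point_cloud> %d points%s\n", nrow(x),
              if ("cwsi" %in% names(x)) " (with CWSI)" else ""))
  if (nrow(x)) {
    cat(sprintf("  temperature [%.1f, %.1f] degC\n",
                min(x$temperature), max(x$temperature)))
  }
  invisible(x)
}

# --- temperature matrices -------------------------------------------------

#' Read a per-pixel temperature matrix
#'
#' Parses the whitespace-separated text dialect used by the thermal camera
#' export: one image row per line, decimal degC values at 0.1 degC
#' resolution, row-major with the origin at the top-left. The tokens `nan`
#' and `NA` mark invalid pixels (present in warped grids).
#'
#' @param path file path.
#' @return numeric matrix (rows x cols as laid out in the file).
#' @export
read_temperature_matrix <- function(path) {
  if (!file.exists(path)) stopf("temperature file does not exist: %s", path)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) stopf("temperature file is empty: %s", path)
  rows <- lapply(seq_along(lines), function(i) {
    toks <- strsplit(trimws(lines[[i]]), "[ \t]+")[[1]]
    vals <- suppressWarnings(as.numeric(toks))
    bad <- which(is.na(vals) & !(toks %in% c("nan", "NaN", "NA", "na")))
    if (length(bad)) {
      stopf("non-numeric token '%s' at row %d, column %d", toks[bad[1]], i, bad[1])
    }
    vals[is.nan(vals)] <- NA_real_
    vals
  })
  ncols <- lengths(rows)
  if (length(unique(ncols)) != 1L) {
    bad <- which(ncols != ncols[1])[1]
    stopf("ragged temperature matrix: row %d has %d values, expected %d",
          bad, ncols[bad], ncols[1])
  }
  matrix(unlist(rows), nrow = length(rows), byrow = TRUE)
}

#' @rdname read_temperature_matrix
#' @param grid numeric matrix of degC values.
#' @export
write_temperature_matrix <- function(grid, path) {
  stopifnot(is.matrix(grid))
  txt <- apply(grid, 1, function(row) {
    paste(ifelse(is.finite(row), sprintf("%.1f", row), "nan"), collapse = " ")
  })
  writeLines(txt, path)
  invisible(path)
}

#' Read a thermal frame from image + temperature files
#'
#' @param image_path PNG pseudo-colour image path.
#' @param temps_path temperature matrix path.
#' @param timestamp optional ISO-8601 string.
#' @export
read_thermal_frame <- function(image_path, temps_path, timestamp = NA_character_) {
  thermal_frame(read_image(image_path), read_temperature_matrix(temps_path),
                timestamp)
}

# --- PLY point clouds -----------------------------------------------------

#' Write and read fused point clouds as PLY
#'
#' Vertices carry `x y z` (float), `red green blue` (uchar),
#' `temperature` (float) and, when present, `cwsi` (float). The default
#' encoding is binary little-endian; `ascii = TRUE` writes the text form.
#' Reading a PLY without a `temperature` vertex property is a format error.
#'
#' @param cloud a [fused_point_cloud()].
#' @param path file path.
#' @param ascii write ASCII PLY instead of binary little-endian.
#' @export
write_point_cloud <- function(cloud, path, ascii = FALSE) {
  stopifnot(inherits(cloud, "fused_point_cloud"))
  has_cwsi <- "cwsi" %in% names(cloud)
  n <- nrow(cloud)
  header <- c(
    "ply",
    if (ascii) "format ascii 1.0" else "format binary_little_endian 1.0",
    "comment canopy3d fused point cloud",
    sprintf("element vertex %d", n),
    "property float x", "property float y", "property float z",
    "property uchar red", "property uchar green", "property uchar blue",
    "property float temperature",
    if (has_cwsi) "property float cwsi",
    "end_header")
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(header, con, sep = "\n")
  if (n == 0) return(invisible(path))
  if (ascii) {
    fmt_row <- function(i) {
      base <- sprintf("%.6g %.6g %.6g %d %d %d %.6g",
                      cloud$x[i], cloud$y[i], cloud$z[i],
                      as.integer(round(cloud$r[i])), as.integer(round(cloud$g[i])),
                      as.integer(round(cloud$b[i])), cloud$temperature[i])
      if (has_cwsi) paste(base, sprintf("%.6g", cloud$cwsi[i])) else base
    }
    writeLines(vapply(seq_len(n), fmt_row, character(1)), con, sep = "\n")
  } else {
    for (i in seq_len(n)) {
      writeBin(as.numeric(c(cloud$x[i], cloud$y[i], cloud$z[i])), con,
               size = 4, endian = "little")
      writeBin(as.raw(round(c(cloud$r[i], cloud$g[i], cloud$b[i]))), con)
      vals <- cloud$temperature[i]
      if (has_cwsi) vals <- c(vals, cloud$cwsi[i])
      writeBin(as.numeric(vals), con, size = 4, endian = "little")
    }
  }
  invisible(path)
}

#' @rdname write_point_cloud
#' @export
read_point_cloud <- function(path) {
  if (!file.exists(path)) stopf("PLY file does not exist: %s", path)
  con <- file(path, open = "rb")
  on.exit(close(con))
  header <- character()
  repeat {
    line <- readBinLine(con)
    header <- c(header, line)
    if (identical(line, "end_header")) break
    if (length(header) > 200) stopf("PLY header not terminated")
  }
  if (!identical(header[1], "ply")) stopf("not a PLY file: %s", path)
  fmt <- header[grepl("^format ", header)][1]
  ascii <- grepl("ascii", fmt)
  n <- as.integer(sub("element vertex ", "", header[grepl("^element vertex", header)][1]))
  props <- sub("^property ", "", header[grepl("^property ", header)])
  prop_types <- vapply(strsplit(props, " "), `[`, character(1), 1L)
  prop_names <- vapply(strsplit(props, " "), `[`, character(1), 2L)
  if (!"temperature" %in% prop_names) {
    stopf("PLY lacks the 'temperature' vertex property: %s", path)
  }
  if (ascii) {
    if (n > 0) {
      txt <- readLines(con, n = n)
      vals <- do.call(rbind, lapply(strsplit(trimws(txt), "[ \t]+"), as.numeric))
    } else vals <- matrix(numeric(), 0, length(prop_names))
  } else {
    vals <- matrix(0, n, length(prop_names))
    if (n > 0) {
      for (i in seq_len(n)) {
        for (j in seq_along(prop_names)) {
          vals[i, j] <- if (prop_types[j] == "uchar") {
            as.numeric(readBin(con, "raw", n = 1))
          } else {
            readBin(con, "numeric", n = 1, size = 4, endian = "little")
          }
        }
      }
    }
  }
  colnames(vals) <- prop_names
  get <- function(nm) if (nm %in% prop_names) vals[, nm] else NULL
  fused_point_cloud(x = vals[, "x"], y = vals[, "y"], z = vals[, "z"],
                    r = get("red"), g = get("green"), b = get("blue"),
                    temperature = vals[, "temperature"], cwsi = get("cwsi"))
}

readBinLine <- function(con) {
  out <- raw()
  repeat {
    ch <- readBin(con, "raw", n = 1)
    if (!length(ch) || ch == as.raw(10)) break
    out <- c(out, ch)
  }
  rawToChar(out)
}

# --- calibration ----------------------------------------------------------

#' Rig calibration
#'
#' Intrinsics of the left, right and thermal cameras plus the relative
#' orientation (rotation `R`, translation `T` in mm) left-to-right and
#' left-to-thermal, and the stereo baseline in mm. A point `p` in the left
#' camera frame maps to `R %*% p + T` in the other camera's frame.
#'
#' @param cameras named list (`left`, `right`, `thermal`) of intrinsics;
#'   each has `f` (focal length, px), `cx`, `cy` (principal point, 0-based
#'   px), `width`, `height` and `dist` (5 radial/tangential coefficients
#'   `k1 k2 p1 p2 k3`).
#' @param left_to_right,left_to_thermal lists with `R` (3x3 orthonormal)
#'   and `T` (length-3, mm).
#' @param baseline_mm stereo baseline, mm (> 0).
#' @return object of class `rig_calibration`.
#' @export
rig_calibration <- function(cameras, left_to_right, left_to_thermal, baseline_mm) {
  for (nm in c("left", "right", "thermal")) {
    cam <- cameras[[nm]]
    if (is.null(cam)) stopf("calibration missing camera '%s'", nm)
    for (fld in c("f", "cx", "cy", "width", "height")) {
      if (is.null(cam[[fld]])) stopf("camera '%s' missing field '%s'", nm, fld)
    }
    if (cam$f <= 0) stopf("camera '%s' has non-positive focal length", nm)
    cameras[[nm]]$dist <- as.numeric(cam$dist %||% numeric(5))
  }
  for (nm in c("left_to_right", "left_to_thermal")) {
    rel <- get(nm)
    if (is.null(rel$R) || is.null(rel$T)) stopf("%s missing R or T", nm)
    # YAML yields a list of three row vectors; JSON (simplifyVector) may
    # already deliver a 3x3 matrix with the rows in place
    rel$R <- if (is.matrix(rel$R)) {
      matrix(as.numeric(rel$R), 3, 3)
    } else {
      matrix(as.numeric(unlist(rel$R)), 3, 3, byrow = TRUE)
    }
    check_orthonormal(rel$R, what = paste0(nm, "$R"))
    rel$T <- as.numeric(unlist(rel$T))
    stopifnot(length(rel$T) == 3L)
    assign(nm, rel)
  }
  if (!is_scalar_number(baseline_mm) || baseline_mm <= 0) {
    stopf("baseline_mm must be a positive number")
  }
  structure(list(cameras = cameras, left_to_right = left_to_right,
                 left_to_thermal = left_to_thermal,
                 baseline_mm = baseline_mm),
            class = "rig_calibration")
}

#' @export
print.rig_calibration <- function(x, ...) {
  cat(sprintf("<rig_calibration> baseline %.1f mm; colour %dx%d f=%.1f px; thermal %dx%d f=%.1f px\n",
              x$baseline_mm,
              x$cameras$left$width, x$cameras$left$height, x$cameras$left$f,
              x$cameras$thermal$width, x$cameras$thermal$height, x$cameras$thermal$f))
  invisible(x)
}

# 3x3 intrinsic matrix of a camera entry.
intrinsic_matrix <- function(cam) {
  matrix(c(cam$f, 0, cam$cx, 0, cam$f, cam$cy, 0, 0, 1), 3, 3, byrow = TRUE)
}

#' Read / write rig calibration files
#'
#' YAML (`.yaml`/`.yml`) or JSON (`.json`) by extension. The schema mirrors
#' [rig_calibration()]: keys `cameras` (with `left`, `right`, `thermal`),
#' `left_to_right`, `left_to_thermal` (each with `R` as 3 rows of 3, `T` as
#' 3 values) and `baseline_mm`. All invariants are validated on load.
#'
#' @param path file path.
#' @export
read_calibration <- function(path) {
  obj <- read_structured(path)
  for (key in c("cameras", "left_to_right", "left_to_thermal", "baseline_mm")) {
    if (is.null(obj[[key]])) stopf("calibration file missing key '%s'", key)
  }
  rig_calibration(obj$cameras, obj$left_to_right, obj$left_to_thermal,
                  obj$baseline_mm)
}

#' @rdname read_calibration
#' @param calib a `rig_calibration`.
#' @export
write_calibration <- function(calib, path) {
  stopifnot(inherits(calib, "rig_calibration"))
  obj <- unclass(calib)
  obj$left_to_right$R <- split_rows(obj$left_to_right$R)
  obj$left_to_thermal$R <- split_rows(obj$left_to_thermal$R)
  write_structured(obj, path)
}

split_rows <- function(m) lapply(seq_len(nrow(m)), function(i) as.numeric(m[i, ]))

read_structured <- function(path) {
  if (!file.exists(path)) stopf("file does not exist: %s", path)
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("yaml", "yml")) {
    yaml::read_yaml(path)
  } else if (ext == "json") {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    stopf("unsupported calibration/config format '.%s' (use YAML or JSON)", ext)
  }
}

write_structured <- function(obj, path) {
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("yaml", "yml")) {
    # full precision: rotation orthonormality must survive the round-trip
    yaml::write_yaml(obj, path, precision = 15)
  } else if (ext == "json") {
    jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  } else {
    stopf("unsupported output format '.%s'", ext)
  }
  invisible(path)
}

# --- pipeline configuration ----------------------------------------------

#' Default pipeline configuration
#'
#' All tunable constants of the pipeline with their default values:
#' HSV canopy thresholds (hue 35--100 on the 0--180 scale; lower saturation
#' bound 35 under direct sun, 60 otherwise), feature-matching ratio test,
#' epipolar row tolerance, RANSAC settings, the fine-registration search
#' grid, stereo matcher parameters, disparity median window and hole-filling
#' initial window, statistical-outlier-removal neighbourhood (k = 50,
#' std ratio = 0.5), k-means settings and the dry-reference offset
#' (air temperature + 7 degC).
#'
#' @return object of class `pipeline_config` (a nested list).
#' @export
default_config <- function() {
  cfg <- list(
    hsv = list(HL = 35, HU = 100, SL_direct = 35, SL_shade = 60, SU = 255,
               VL = 0, VU = 255),
    sun = list(mode = "auto", illumination_threshold_klx = 50),
    matching = list(ratio_threshold = 0.7, epipolar_row_tol = 2,
                    max_keypoints = 500),
    ransac = list(reproj_threshold = 3, max_iter = 2000, confidence = 0.995,
                  seed = 1),
    fine = list(search_range = 10, step = 1),
    # min/num disparities NULL = derive from the rig's working range,
    # see stereo_params_for_rig()
    stereo = list(block_size = 5, min_disparity = NULL,
                  num_disparities = NULL, p1 = NULL, p2 = NULL,
                  uniqueness_ratio = 10, lr_max_diff = 1),
    disparity = list(median_window = 3, fill_initial_window = 4),
    cleaning = list(outlier_k = 50, outlier_std_ratio = 0.5, kmeans_seed = 1,
                    degenerate_spread = 0.2),
    cwsi = list(dry_offset = 7, wet_roi = NULL, time_join_tolerance_min = 5)
  )
  structure(cfg, class = "pipeline_config")
}

#' Load a pipeline configuration file
#'
#' Reads YAML or JSON and merges it over [default_config()]; unspecified
#' keys keep their defaults (in particular, an omitted dry-reference offset
#' defaults to 7 degC). Basic domain checks are applied after merging.
#'
#' @param path file path, or `NULL` for pure defaults.
#' @export
load_config <- function(path = NULL) {
  cfg <- default_config()
  if (!is.null(path)) {
    user <- read_structured(path)
    cfg <- modify_list_deep(cfg, user)
    class(cfg) <- "pipeline_config"
  }
  validate_config(cfg)
  cfg
}

modify_list_deep <- function(base, new) {
  for (nm in names(new)) {
    if (is.list(new[[nm]]) && is.list(base[[nm]])) {
      base[[nm]] <- modify_list_deep(base[[nm]], new[[nm]])
    } else {
      base[[nm]] <- new[[nm]]
    }
  }
  base
}

validate_config <- function(cfg) {
  h <- cfg$hsv
  if (!(h$HL < h$HU)) stopf("config: HL must be < HU")
  if (!(h$SL_direct <= h$SU && h$SL_shade <= h$SU)) stopf("config: SL must be <= SU")
  if (!(h$VL < h$VU)) stopf("config: VL must be < VU")
  if (!(cfg$matching$ratio_threshold > 0 && cfg$matching$ratio_threshold < 1)) {
    stopf("config: ratio_threshold must be in (0,1)")
  }
  if (cfg$fine$step < 1) stopf("config: fine-search step must be >= 1 px")
  if (!is.null(cfg$stereo$num_disparities) &&
      cfg$stereo$num_disparities %% 16 != 0) {
    stopf("config: num_disparities must be a multiple of 16")
  }
  if (cfg$disparity$fill_initial_window < 3) {
    stopf("config: fill_initial_window must be >= 3")
  }
  invisible(cfg)
}
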