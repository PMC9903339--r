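#' Reference temperatures for CWSI
#'
#' The wet reference is the temperature of a fully transpiring surface;
#' the dry reference is approximated by air temperature plus a fixed
#' offset (7 degC by default). Requires `T_dry > T_wet`.
#'
#' @param T_wet wet-reference temperature, degC.
#' @param T_air air temperature, degC.
#' @param dry_offset dry-reference offset above air temperature, degC.
#' @return object of class `reference_temperatures` with `T_wet`, `T_dry`,
#'   `T_air`, `dry_offset`.
#' @export
reference_temperatures <- function(T_wet, T_air, dry_offset = 7) {
  if (!is_scalar_number(T_wet) || !is_scalar_number(T_air)) {
    stopf("T_wet and T_air must be finite numbers")
  }
  T_dry <- dry_reference(T_air, dry_offset)
  if (T_dry <= T_wet) {
    stopf("invalid references: T_dry (%.2f) must exceed T_wet (%.2f)",
          T_dry, T_wet)
  }
  structure(list(T_wet = T_wet, T_dry = T_dry, T_air = T_air,
                 dry_offset = dry_offset),
            class = "reference_temperatures")
}

#' Dry-reference temperature
#'
#' `T_dry = T_air + offset` (default offset 7 degC).
#'
#' @param T_air air temperature, degC (finite).
#' @param offset offset in degC.
#' @export
dry_reference <- function(T_air, offset = 7) {
  if (!is_scalar_number(T_air)) stopf("T_air must be a finite number")
  T_air + offset
}

#' Wet-reference temperature from a region of interest
#'
#' Mean of the valid temperatures inside the ROI. The source is either a
#' temperature matrix with a pixel box `c(x0, y0, x1, y1)` (0-based,
#' inclusive) or a [fused_point_cloud()] with a 3D box
#' `list(x = c(lo, hi), y = ..., z = ...)`.
#'
#' @param source temperature matrix or `fused_point_cloud`.
#' @param roi pixel box or 3D box, see Details.
#' @return mean temperature, degC.
#' @export
wet_reference_from_roi <- function(source, roi) {
  if (inherits(source, "fused_point_cloud")) {
    stopifnot(is.list(roi), all(c("x", "y", "z") %in% names(roi)))
    sel <- source$x >= roi$x[1] & source$x <= roi$x[2] &
      source$y >= roi$y[1] & source$y <= roi$y[2] &
      source$z >= roi$z[1] & source$z <= roi$z[2]
    vals <- source$temperature[sel]
  } else {
    stopifnot(is.matrix(source), length(roi) == 4)
    x0 <- roi[1]; y0 <- roi[2]; x1 <- roi[3]; y1 <- roi[4]
    h <- nrow(source); w <- ncol(source)
    if (x0 < 0 || y0 < 0 || x1 >= w || y1 >= h || x1 < x0 || y1 < y0) {
      stopf("wet-reference ROI [%g,%g,%g,%g] outside the %dx%d grid",
            x0, y0, x1, y1, w, h)
    }
    vals <- source[(y0 + 1):(y1 + 1), (x0 + 1):(x1 + 1)]
  }
  vals <- vals[is.finite(vals)]
  if (!length(vals)) stopf("wet-reference ROI contains no valid temperature")
  mean(vals)
}

#' Per-point CWSI
#'
#' `CWSI = (T_c - T_wet) / (T_dry - T_wet)`, clamped to [0, 1]. The number
#' of clamped values is recorded in `attr(, "n_clamped")` so measurement
#' noise pushing past the references is visible rather than hidden.
#'
#' @param T_c canopy temperature(s), degC.
#' @param refs a [reference_temperatures()].
#' @return CWSI values in [0, 1].
#' @export
compute_cwsi_point <- function(T_c, refs) {
  stopifnot(inherits(refs, "reference_temperatures"))
  raw <- (T_c - refs$T_wet) / (refs$T_dry - refs$T_wet)
  clamped <- raw < 0 | raw > 1
  structure(pmin(pmax(raw, 0), 1), n_clamped = sum(clamped, na.rm = TRUE))
}

#' CWSI field over a point cloud
#'
#' Adds a `cwsi` column computed per point from its temperature; the
#' fraction of clamped points is reported in `attr(, "clamp_fraction")`.
#'
#' @param cloud a [fused_point_cloud()] with temperatures.
#' @param refs a [reference_temperatures()].
#' @export
compute_cwsi_field <- function(cloud, refs) {
  stopifnot(inherits(cloud, "fused_point_cloud"))
  v <- compute_cwsi_point(cloud$temperature, refs)
  out <- cloud
  out$cwsi <- as.numeric(v)
  attr(out, "clamp_fraction") <- if (nrow(cloud)) {
    attr(v, "n_clamped") / nrow(cloud)
  } else 0
  out
}

#' Canopy summary of a CWSI field
#'
#' @param field a `fused_point_cloud` with a `cwsi` column.
#' @param timestamp ISO-8601 string.
#' @param T_air air temperature, degC (optional).
#' @param illumination_klx illumination, klx (optional).
#' @param group label, e.g. `"well_watered"` / `"stressed"`.
#' @return one-row data frame: `timestamp`, `group`, `mean_cwsi`, `n`,
#'   `T_air`, `illumination_klx`.
#' @export
canopy_mean_cwsi <- function(field, timestamp = NA_character_, T_air = NA_real_,
                             illumination_klx = NA_real_, group = "canopy") {
  stopifnot(inherits(field, "fused_point_cloud"), "cwsi" %in% names(field))
  if (!nrow(field)) stopf("canopy_mean_cwsi: empty field")
  data.frame(timestamp = timestamp, group = group,
             mean_cwsi = mean(field$cwsi), n = nrow(field),
             T_air = T_air, illumination_klx = illumination_klx,
             stringsAsFactors = FALSE)
}

#' Assemble a CWSI time series with environment records
#'
#' Joins canopy summaries (one row per timestamp and group) with an
#' environment table (`time`, `t_air`, `illumination_klx`) by nearest
#' timestamp within a tolerance; summaries with no environment row inside
#' the tolerance keep `NA` environment fields and raise a warning. Mean
#' CWSI is spread into one column per group (`cwsi_<group>`), ordered by
#' time.
#'
#' @param summaries data frame of [canopy_mean_cwsi()] rows.
#' @param environment data frame with `time`, `t_air`,
#'   `illumination_klx` (e.g. read from CSV).
#' @param tolerance_min join tolerance in minutes.
#' @return data frame: `time`, one `cwsi_*` column per group, `t_air`,
#'   `illumination_klx`.
#' @export
assemble_time_series <- function(summaries, environment = NULL,
                                 tolerance_min = 5) {
  stopifnot(nrow(summaries) >= 1)
  st <- as.POSIXct(summaries$timestamp, tz = "UTC")
  if (anyNA(st)) stopf("assemble_time_series: unparseable summary timestamps")
  groups <- unique(summaries$group)
  times <- sort(unique(st))
  out <- data.frame(time = times)
  for (g in groups) {
    col <- rep(NA_real_, length(times))
    rows <- summaries$group == g
    idx <- match(st[rows], times)
    col[idx] <- summaries$mean_cwsi[rows]
    out[[paste0("cwsi_", g)]] <- col
  }
  out$t_air <- NA_real_
  out$illumination_klx <- NA_real_
  if (!is.null(environment) && nrow(environment)) {
    et <- as.POSIXct(environment$time, tz = "UTC")
    for (i in seq_along(times)) {
      dt <- abs(as.numeric(difftime(times[i], et, units = "mins")))
      j <- which.min(dt)
      if (dt[j] <= tolerance_min) {
        out$t_air[i] <- environment$t_air[j]
        out$illumination_klx[i] <- environment$illumination_klx[j]
      } else {
        warning(sprintf("no environment record within %g min of %s",
                        tolerance_min, format(times[i])), call. = FALSE)
      }
    }
  }
  out[order(out$time), , drop = FALSE]
}
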