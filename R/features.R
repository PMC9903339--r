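# Scale- and rotation-invariant interest points with floating-point
# descriptors: a compact difference-of-Gaussians detector with subpixel
# localization, dominant-orientation assignment and 4x4x8
# gradient-orientation-histogram descriptors. Fills the role the
# registration chain needs (SURF-class detector); the detector name is
# recorded in the match-set metadata.

shift_pad <- function(m, dy, dx, fill) {
  h <- nrow(m); w <- ncol(m)
  out <- matrix(fill, h, w)
  ys <- max(1, 1 - dy):min(h, h - dy)
  xs <- max(1, 1 - dx):min(w, w - dx)
  out[ys, xs] <- m[ys + dy, xs + dx]
  out
}

neigh_max8 <- function(m) {
  p <- function(dy, dx) shift_pad(m, dy, dx, -Inf)
  pmax(p(-1, -1), p(-1, 0), p(-1, 1), p(0, -1), p(0, 1),
       p(1, -1), p(1, 0), p(1, 1))
}

neigh_max9 <- function(m) pmax(neigh_max8(m), m)

neigh_min8 <- function(m) -neigh_max8(-m)
neigh_min9 <- function(m) -neigh_max9(-m)

#' Detect scale-space keypoints
#'
#' Difference-of-Gaussians extrema over a small octave pyramid with edge
#' suppression and subpixel (quadratic) localization, followed by a
#' dominant gradient orientation per keypoint.
#'
#' @param gray grayscale matrix (0--255).
#' @param max_keypoints keep at most this many, strongest first.
#' @param n_octaves number of pyramid octaves.
#' @param contrast_threshold minimum |DoG| response (on 0--1 intensities).
#' @return data frame with 0-based `x`, `y`, `sigma`, `angle` (radians),
#'   `response`, plus internal octave/level indices.
#' @export
detect_keypoints <- function(gray, max_keypoints = 500, n_octaves = 3,
                             contrast_threshold = 0.01) {
  g <- gray / 255
  sigma0 <- 1.6
  k <- sqrt(2)
  n_levels <- 5L
  pyr <- list()
  base <- gaussian_blur(g, sigma0)
  kps <- list()
  for (o in seq_len(n_octaves) - 1L) {
    if (min(dim(base)) < 16) break
    levels <- vector("list", n_levels)
    levels[[1]] <- base
    for (s in 2:n_levels) {
      # incremental blur from sigma0*k^(s-2) to sigma0*k^(s-1)
      sig_inc <- sigma0 * k^(s - 2) * sqrt(k^2 - 1)
      levels[[s]] <- gaussian_blur(levels[[s - 1]], sig_inc)
    }
    dog <- lapply(1:(n_levels - 1), function(s) levels[[s + 1]] - levels[[s]])
    for (s in 2:(n_levels - 2)) {
      D <- dog[[s]]
      up <- dog[[s + 1]]; dn <- dog[[s - 1]]
      is_max <- D > neigh_max8(D) & D > neigh_max9(up) & D > neigh_max9(dn) &
        D > contrast_threshold
      is_min <- D < neigh_min8(D) & D < neigh_min9(up) & D < neigh_min9(dn) &
        D < -contrast_threshold
      cand <- which(is_max | is_min, arr.ind = TRUE)
      if (!nrow(cand)) next
      # drop border candidates (descriptor support must fit loosely)
      keep <- cand[, 1] > 2 & cand[, 1] < nrow(D) - 1 &
        cand[, 2] > 2 & cand[, 2] < ncol(D) - 1
      cand <- cand[keep, , drop = FALSE]
      if (!nrow(cand)) next
      ij <- cand
      off <- function(dy, dx) cbind(ij[, 1] + dy, ij[, 2] + dx)
      # edge rejection via 2x2 spatial Hessian of D
      dxx <- D[off(0, 1)] + D[off(0, -1)] - 2 * D[ij]
      dyy <- D[off(1, 0)] + D[off(-1, 0)] - 2 * D[ij]
      dxy <- (D[off(1, 1)] + D[off(-1, -1)] - D[off(1, -1)] - D[off(-1, 1)]) / 4
      tr <- dxx + dyy; det <- dxx * dyy - dxy^2
      r_edge <- 10
      ok_edge <- det > 0 & tr^2 / det < (r_edge + 1)^2 / r_edge
      ij <- ij[ok_edge, , drop = FALSE]
      if (!nrow(ij)) next
      dxx <- dxx[ok_edge]; dyy <- dyy[ok_edge]; dxy <- dxy[ok_edge]
      off <- function(dy, dx) cbind(ij[, 1] + dy, ij[, 2] + dx)
      gx <- (D[off(0, 1)] - D[off(0, -1)]) / 2
      gy <- (D[off(1, 0)] - D[off(-1, 0)]) / 2
      det2 <- dxx * dyy - dxy^2
      det2[abs(det2) < 1e-12] <- NA
      offx <- -(dyy * gx - dxy * gy) / det2
      offy <- -(-dxy * gx + dxx * gy) / det2
      ok_off <- is.finite(offx) & is.finite(offy) & abs(offx) <= 1 & abs(offy) <= 1
      ij <- ij[ok_off, , drop = FALSE]
      if (!nrow(ij)) next
      offx <- offx[ok_off]; offy <- offy[ok_off]
      sig_level <- sigma0 * k^(s - 1)
      kp <- data.frame(
        x = (ij[, 2] - 1 + offx) * 2^o,
        y = (ij[, 1] - 1 + offy) * 2^o,
        sigma = sig_level * 2^o,
        response = abs(D[ij]),
        octave = o, level = s,
        xi = ij[, 2] - 1L, yi = ij[, 1] - 1L)
      kps[[length(kps) + 1]] <- kp
    }
    pyr[[o + 1]] <- levels
    base <- levels[[n_levels - 2]][seq(1, nrow(base), 2), seq(1, ncol(base), 2)]
  }
  if (!length(kps)) {
    return(structure(data.frame(x = numeric(), y = numeric(), sigma = numeric(),
                                angle = numeric(), response = numeric()),
                     pyramid = pyr))
  }
  kp <- do.call(rbind, kps)
  kp <- kp[order(-kp$response), , drop = FALSE]
  if (nrow(kp) > max_keypoints) kp <- kp[seq_len(max_keypoints), , drop = FALSE]
  # gradient fields per (octave, level), reused for orientation + descriptors
  grads <- gradient_fields(pyr)
  kp$angle <- keypoint_orientation(kp, grads)
  structure(kp, pyramid = pyr, gradients = grads)
}

gradient_fields <- function(pyr) {
  lapply(pyr, function(levels) {
    lapply(levels, function(L) {
      gx <- (shift_pad(L, 0, 1, NA) - shift_pad(L, 0, -1, NA)) / 2
      gy <- (shift_pad(L, 1, 0, NA) - shift_pad(L, -1, 0, NA)) / 2
      gx[is.na(gx)] <- 0; gy[is.na(gy)] <- 0
      list(gx = gx, gy = gy)
    })
  })
}

keypoint_orientation <- function(kp, grads) {
  n_bins <- 36L
  angles <- numeric(nrow(kp))
  for (i in seq_len(nrow(kp))) {
    o <- kp$octave[i]; s <- kp$level[i]
    gr <- grads[[o + 1]][[s]]
    sig <- kp$sigma[i] / 2^o
    r <- max(3L, round(2.5 * sig))
    x0 <- kp$xi[i]; y0 <- kp$yi[i]
    h <- nrow(gr$gx); w <- ncol(gr$gx)
    xs <- max(0, x0 - r):min(w - 1, x0 + r)
    ys <- max(0, y0 - r):min(h - 1, y0 + r)
    gx <- gr$gx[ys + 1, xs + 1, drop = FALSE]
    gy <- gr$gy[ys + 1, xs + 1, drop = FALSE]
    dmx <- matrix(rep(xs - x0, each = length(ys)), length(ys))
    dmy <- matrix(rep(ys - y0, times = length(xs)), length(ys))
    wgt <- exp(-(dmx^2 + dmy^2) / (2 * (1.5 * sig)^2))
    mag <- sqrt(gx^2 + gy^2) * wgt
    ang <- atan2(gy, gx) %% (2 * pi)
    bin <- floor(ang / (2 * pi) * n_bins) %% n_bins
    hist <- vapply(0:(n_bins - 1), function(b) sum(mag[bin == b]), numeric(1))
    # circular smooth
    hs <- (hist + c(tail(hist, 1), head(hist, -1)) +
             c(tail(hist, -1), head(hist, 1))) / 3
    b <- which.max(hs) - 1L
    l <- hs[(b - 1) %% n_bins + 1]; c0 <- hs[b + 1]; rgt <- hs[(b + 1) %% n_bins + 1]
    denom <- l - 2 * c0 + rgt
    off <- if (abs(denom) > 1e-12) 0.5 * (l - rgt) / denom else 0
    angles[i] <- ((b + off) / n_bins * 2 * pi) %% (2 * pi)
  }
  angles
}

#' Compute descriptors for detected keypoints
#'
#' 4x4 spatial cells of 8-bin gradient-orientation histograms sampled on a
#' grid rotated to the keypoint's dominant orientation, Gaussian-weighted,
#' normalized, clipped at 0.2 and renormalized (128-dimensional,
#' floating point).
#'
#' @param kp result of [detect_keypoints()] (carries its pyramid).
#' @return numeric matrix `nrow(kp) x 128`.
#' @export
compute_descriptors <- function(kp) {
  grads <- attr(kp, "gradients")
  n <- nrow(kp)
  desc <- matrix(0, n, 128)
  if (!n) return(desc)
  n_cells <- 4L; n_ori <- 8L
  gs <- 4L  # samples per cell side
  side <- n_cells * gs  # 16x16 samples
  u <- (seq_len(side) - (side + 1) / 2)  # sample offsets in cell units/gs
  grid <- expand.grid(ux = u, uy = u)
  for (i in seq_len(n)) {
    o <- kp$octave[i]; s <- kp$level[i]
    gr <- grads[[o + 1]][[s]]
    sig <- kp$sigma[i] / 2^o
    cell_px <- max(1, 0.9 * sig)        # cell side in octave px
    step <- cell_px / gs
    th <- kp$angle[i]
    ct <- cos(th); st <- sin(th)
    rx <- (grid$ux * ct - grid$uy * st) * step
    ry <- (grid$ux * st + grid$uy * ct) * step
    px <- kp$xi[i] + rx
    py <- kp$yi[i] + ry
    gx <- bilinear_sample(gr$gx, px, py)
    gy <- bilinear_sample(gr$gy, px, py)
    ok <- is.finite(gx) & is.finite(gy)
    if (!any(ok)) next
    mag <- sqrt(gx^2 + gy^2)
    ang <- (atan2(gy, gx) - th) %% (2 * pi)
    wgt <- exp(-(grid$ux^2 + grid$uy^2) / (2 * (side / 2)^2))
    cellx <- pmin(floor((grid$ux + side / 2) / gs), n_cells - 1)
    celly <- pmin(floor((grid$uy + side / 2) / gs), n_cells - 1)
    obin <- ang / (2 * pi) * n_ori
    b0 <- floor(obin) %% n_ori
    fo <- obin - floor(obin)
    d <- numeric(128)
    idx0 <- (celly * n_cells + cellx) * n_ori + b0 + 1
    idx1 <- (celly * n_cells + cellx) * n_ori + ((b0 + 1) %% n_ori) + 1
    w0 <- mag * wgt * (1 - fo)
    w1 <- mag * wgt * fo
    for (j in which(ok)) {
      d[idx0[j]] <- d[idx0[j]] + w0[j]
      d[idx1[j]] <- d[idx1[j]] + w1[j]
    }
    nrm <- sqrt(sum(d^2))
    if (nrm > 1e-12) d <- d / nrm
    d <- pmin(d, 0.2)
    nrm <- sqrt(sum(d^2))
    if (nrm > 1e-12) d <- d / nrm
    desc[i, ] <- d
  }
  desc
}

#' Detect and match features between two images
#'
#' Detects keypoints and descriptors in both images and matches them with
#' the nearest-neighbour distance-ratio strategy: a pair is kept when the
#' best descriptor distance is below `ratio_threshold` times the
#' second-best. Textureless inputs yield an empty set, not an error.
#'
#' @param left,right grayscale matrices or colour arrays (converted to
#'   luminance).
#' @param ratio_threshold ratio-test threshold in (0, 1).
#' @param max_keypoints per-image keypoint cap.
#' @return a `feature_match_set`: data frame with `xl, yl, xr, yr`
#'   (0-based pixel coordinates) and `distance`; detector name in
#'   `attr(, "detector")`.
#' @export
detect_and_match_features <- function(left, right, ratio_threshold = 0.7,
                                      max_keypoints = 500) {
  if (!all(dim(to_gray(left)) == dim(to_gray(right)))) {
    stopf("left and right images differ in size")
  }
  stopifnot(ratio_threshold > 0, ratio_threshold < 1)
  kl <- detect_keypoints(to_gray(left), max_keypoints)
  kr <- detect_keypoints(to_gray(right), max_keypoints)
  empty <- structure(data.frame(xl = numeric(), yl = numeric(),
                                xr = numeric(), yr = numeric(),
                                distance = numeric()),
                     class = c("feature_match_set", "data.frame"),
                     detector = "dog-ogh")
  if (!nrow(kl) || !nrow(kr)) return(empty)
  dl <- compute_descriptors(kl)
  dr <- compute_descriptors(kr)
  d2 <- outer(rowSums(dl^2), rep(1, nrow(dr))) +
    outer(rep(1, nrow(dl)), rowSums(dr^2)) - 2 * tcrossprod(dl, dr)
  d2[d2 < 0] <- 0
  matches <- lapply(seq_len(nrow(dl)), function(i) {
    ord <- order(d2[i, ])
    best <- ord[1]
    d1 <- sqrt(d2[i, best])
    d2nd <- if (length(ord) > 1) sqrt(d2[i, ord[2]]) else Inf
    if (d1 < ratio_threshold * d2nd) c(i, best, d1) else NULL
  })
  matches <- do.call(rbind, matches)
  if (is.null(matches)) return(empty)
  out <- data.frame(xl = kl$x[matches[, 1]], yl = kl$y[matches[, 1]],
                    xr = kr$x[matches[, 2]], yr = kr$y[matches[, 2]],
                    distance = matches[, 3])
  structure(out, class = c("feature_match_set", "data.frame"),
            detector = "dog-ogh")
}
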