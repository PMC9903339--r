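#' Image conventions
#'
#' Images are numeric arrays in the 0--255 range: colour images have
#' dimensions `c(height, width, 3)` and grayscale images are
#' `height x width` matrices. Pixel coordinates are 0-based with the origin
#' at the top-left corner, `x` increasing rightward (columns) and `y`
#' increasing downward (rows), so pixel `(x, y)` is element
#' `[y + 1, x + 1]`. All geometric operations (resampling, warping,
#' projection) treat integer coordinates as pixel centres.
#'
#' @name image-conventions
NULL

#' Read and write images
#'
#' PNG-backed readers/writers for the 0--255 array convention used
#' throughout the package.
#'
#' @param path file path.
#' @param image colour array (`h x w x 3`) or grayscale matrix, values 0--255.
#' @return `read_image()` returns an `h x w x 3` numeric array in 0--255.
#' @export
read_image <- function(path) {
  if (!file.exists(path)) stopf("image file does not exist: %s", path)
  img <- png::readPNG(path)
  if (length(dim(img)) == 2L) {
    img <- array(rep(img, 3L), dim = c(dim(img), 3L))
  } else if (dim(img)[3] >= 3L) {
    img <- img[, , 1:3, drop = FALSE]
  } else {
    img <- array(rep(img[, , 1L], 3L), dim = c(dim(img)[1:2], 3L))
  }
  img * 255
}

#' @rdname read_image
#' @export
write_image <- function(image, path) {
  img <- clamp01(image / 255)
  png::writePNG(img, path)
  invisible(path)
}

clamp01 <- function(x) pmin(pmax(x, 0), 1)

clamp255 <- function(x) pmin(pmax(x, 0), 255)

#' Convert a colour image to grayscale luminance
#'
#' Uses the Rec. 601 weights 0.299 R + 0.587 G + 0.114 B.
#'
#' @param image `h x w x 3` array in 0--255, or a matrix (returned as is).
#' @return grayscale matrix in 0--255.
#' @export
to_gray <- function(image) {
  if (is.matrix(image)) return(image)
  stopifnot(length(dim(image)) == 3L)
  0.299 * image[, , 1] + 0.587 * image[, , 2] + 0.114 * image[, , 3]
}

#' Convert RGB values to the HSV scale used for segmentation
#'
#' Hue is reported on the 0--180 half-degree scale and saturation/value on
#' 0--255, matching the convention the segmentation thresholds are written
#' in.
#'
#' @param r,g,b numeric vectors in 0--255.
#' @return list with components `h` (0--180), `s` (0--255), `v` (0--255).
#' @export
rgb_to_hsv180 <- function(r, g, b) {
  hsv <- grDevices::rgb2hsv(rbind(as.numeric(r), as.numeric(g), as.numeric(b)),
                            maxColorValue = 255)
  list(h = hsv[1, ] * 180, s = hsv[2, ] * 255, v = hsv[3, ] * 255)
}

# --- sampling -------------------------------------------------------------

# Bilinear sample of matrix `mat` at 0-based (x, y); outside the source
# raster returns NA.
bilinear_sample <- function(mat, x, y) {
  h <- nrow(mat); w <- ncol(mat)
  out <- rep(NA_real_, length(x))
  ok <- is.finite(x) & is.finite(y) & x >= 0 & x <= w - 1 & y >= 0 & y <= h - 1
  if (!any(ok)) return(out)
  x <- x[ok]; y <- y[ok]
  x0 <- pmin(floor(x), w - 2); y0 <- pmin(floor(y), h - 2)
  fx <- x - x0; fy <- y - y0
  i00 <- (x0) * h + y0 + 1
  v <- (1 - fx) * (1 - fy) * mat[i00] +
    fx * (1 - fy) * mat[i00 + h] +
    (1 - fx) * fy * mat[i00 + 1] +
    fx * fy * mat[i00 + h + 1]
  out[ok] <- v
  out
}

# Nearest-neighbour sample at 0-based (x, y); outside returns NA.
nearest_sample <- function(mat, x, y) {
  h <- nrow(mat); w <- ncol(mat)
  xi <- round(x); yi <- round(y)
  out <- rep(NA_real_, length(x))
  ok <- is.finite(xi) & is.finite(yi) & xi >= 0 & xi <= w - 1 & yi >= 0 & yi <= h - 1
  out[ok] <- mat[cbind(yi[ok] + 1, xi[ok] + 1)]
  out
}

# Catmull-Rom cubic kernel weights for fractional offset t in [0, 1); returns
# a 4-row matrix of weights for taps at offsets -1, 0, 1, 2.
cubic_weights <- function(t) {
  a <- -0.5
  w <- function(x) {
    x <- abs(x)
    ifelse(x <= 1, (a + 2) * x^3 - (a + 3) * x^2 + 1,
           ifelse(x < 2, a * x^3 - 5 * a * x^2 + 8 * a * x - 4 * a, 0))
  }
  rbind(w(t + 1), w(t), w(1 - t), w(2 - t))
}

# Bicubic (Catmull-Rom) sample of `mat` at 0-based (x, y) with edge
# clamping; outside the raster returns NA.
bicubic_sample <- function(mat, x, y) {
  h <- nrow(mat); w <- ncol(mat)
  out <- rep(NA_real_, length(x))
  ok <- is.finite(x) & is.finite(y) & x >= 0 & x <= w - 1 & y >= 0 & y <= h - 1
  if (!any(ok)) return(out)
  x <- x[ok]; y <- y[ok]
  x0 <- floor(x); y0 <- floor(y)
  fx <- x - x0; fy <- y - y0
  wx <- cubic_weights(fx)  # 4 x n
  wy <- cubic_weights(fy)
  acc <- numeric(length(x))
  for (j in 0:3) {
    xs <- pmin(pmax(x0 + j - 1, 0), w - 1)
    col_acc <- numeric(length(x))
    for (i in 0:3) {
      ys <- pmin(pmax(y0 + i - 1, 0), h - 1)
      col_acc <- col_acc + wy[i + 1, ] * mat[xs * h + ys + 1]
    }
    acc <- acc + wx[j + 1, ] * col_acc
  }
  out[ok] <- acc
  out
}

#' Resize an image with bicubic interpolation
#'
#' Catmull-Rom bicubic resampling with pixel-centre alignment: output pixel
#' `x` samples the input at `(x + 0.5) * w_in / w_out - 0.5`.
#'
#' @param image colour array or grayscale matrix (0--255).
#' @param out_w,out_h output dimensions in pixels.
#' @return resized image, clipped to 0--255.
#' @export
resize_bicubic <- function(image, out_w, out_h) {
  resize_one <- function(mat) {
    h <- nrow(mat); w <- ncol(mat)
    xs <- ((seq_len(out_w) - 0.5) * w / out_w) - 0.5
    ys <- ((seq_len(out_h) - 0.5) * h / out_h) - 0.5
    xg <- rep(xs, each = out_h)
    yg <- rep(ys, times = out_w)
    xg <- pmin(pmax(xg, 0), w - 1)
    yg <- pmin(pmax(yg, 0), h - 1)
    matrix(clamp255(bicubic_sample(mat, xg, yg)), nrow = out_h, ncol = out_w)
  }
  if (is.matrix(image)) return(resize_one(image))
  out <- array(0, dim = c(out_h, out_w, 3L))
  for (c in 1:3) out[, , c] <- resize_one(image[, , c])
  out
}

#' Crop an image
#'
#' @param image colour array or grayscale matrix.
#' @param x0,y0 0-based top-left corner of the crop window.
#' @param w,h crop size in pixels.
#' @export
crop_image <- function(image, x0, y0, w, h) {
  H <- dim(image)[1]; W <- dim(image)[2]
  if (x0 < 0 || y0 < 0 || x0 + w > W || y0 + h > H) {
    stopf("crop window [%d,%d %dx%d] exceeds image bounds %dx%d",
          x0, y0, w, h, W, H)
  }
  rows <- (y0 + 1):(y0 + h)
  cols <- (x0 + 1):(x0 + w)
  if (is.matrix(image)) image[rows, cols, drop = FALSE] else image[rows, cols, , drop = FALSE]
}

# 2D convolution of a matrix with a small kernel, replicate (edge) padding.
convolve2d_replicate <- function(mat, kernel) {
  kh <- nrow(kernel); kw <- ncol(kernel)
  stopifnot(kh %% 2 == 1, kw %% 2 == 1)
  ry <- (kh - 1) %/% 2; rx <- (kw - 1) %/% 2
  h <- nrow(mat); w <- ncol(mat)
  pad <- mat[pmin(pmax(seq_len(h + 2 * ry) - ry, 1), h),
             pmin(pmax(seq_len(w + 2 * rx) - rx, 1), w), drop = FALSE]
  out <- matrix(0, h, w)
  for (i in seq_len(kh)) {
    for (j in seq_len(kw)) {
      k <- kernel[i, j]
      if (k != 0) out <- out + k * pad[(i):(i + h - 1), (j):(j + w - 1)]
    }
  }
  out
}

# Separable Gaussian blur (replicate padding), used by SSIM and the feature
# detector pyramid.
gaussian_blur <- function(mat, sigma, radius = ceiling(3 * sigma)) {
  x <- (-radius):radius
  k <- exp(-x^2 / (2 * sigma^2))
  k <- k / sum(k)
  convolve2d_replicate(convolve2d_replicate(mat, matrix(k, nrow = 1)),
                       matrix(k, ncol = 1))
}
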