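# Independent brute-force oracles (nested loops / direct formulas), kept
# deliberately separate from the implementation paths they check.

# 2D convolution with replicate padding, nested loops.
oracle_convolve2d <- function(mat, kernel) {
  h <- nrow(mat); w <- ncol(mat)
  kh <- nrow(kernel); kw <- ncol(kernel)
  ry <- (kh - 1) %/% 2; rx <- (kw - 1) %/% 2
  out <- matrix(0, h, w)
  for (y in 1:h) for (x in 1:w) {
    acc <- 0
    for (i in 1:kh) for (j in 1:kw) {
      yy <- min(max(y + i - 1 - ry, 1), h)
      xx <- min(max(x + j - 1 - rx, 1), w)
      acc <- acc + kernel[i, j] * mat[yy, xx]
    }
    out[y, x] <- acc
  }
  out
}

# valid-aware median filter, nested loops.
oracle_median_filter <- function(m, window) {
  h <- nrow(m); w <- ncol(m); r <- window %/% 2
  out <- m
  for (y in 1:h) for (x in 1:w) {
    if (!is.finite(m[y, x])) { out[y, x] <- NA_real_; next }
    vals <- c()
    for (i in max(1, y - r):min(h, y + r))
      for (j in max(1, x - r):min(w, x + r))
        if (is.finite(m[i, j])) vals <- c(vals, m[i, j])
    out[y, x] <- median(vals)
  }
  out
}

# multi-level mean fill, nested loops over the documented pass sequence:
# windows initial, ceil/2, ..., plus a final 3x3; sums/counts taken from
# the fill input; even windows anchored floor(W/2) above/left; later
# passes overwrite; originally valid pixels untouched.
oracle_multilevel_fill <- function(m, initial_window) {
  wins <- integer(); W <- initial_window
  while (W > 3) { wins <- c(wins, W); W <- ceiling(W / 2) }
  wins <- c(wins, 3L)
  h <- nrow(m); w <- ncol(m)
  valid0 <- is.finite(m)
  out <- m
  for (W in wins) {
    a <- W %/% 2
    for (y in 1:h) for (x in 1:w) {
      if (valid0[y, x]) next
      ys <- max(1, y - a):min(h, y - a + W - 1)
      xs <- max(1, x - a):min(w, x - a + W - 1)
      vals <- m[ys, xs][valid0[ys, xs]]
      if (length(vals)) out[y, x] <- mean(vals)
    }
  }
  out
}

# quadratic-time statistical outlier removal.
oracle_sor_kept <- function(cloud, k, ratio) {
  n <- nrow(cloud)
  P <- cbind(cloud$x, cloud$y, cloud$z)
  md <- numeric(n)
  for (i in 1:n) {
    d <- sqrt(colSums((t(P) - P[i, ])^2))
    md[i] <- mean(sort(d[-i])[1:k])
  }
  which(md <= mean(md) + ratio * sd(md))
}

# exhaustive optimal 1-D 2-means by threshold scan (minimum within-cluster
# sum of squares over all split points).
oracle_1d_2means <- function(v) {
  sv <- sort(v)
  best <- NULL; best_ss <- Inf
  for (i in 1:(length(sv) - 1)) {
    if (sv[i] == sv[i + 1]) next
    thr <- (sv[i] + sv[i + 1]) / 2
    lo <- v[v <= thr]; hi <- v[v > thr]
    ss <- sum((lo - mean(lo))^2) + sum((hi - mean(hi))^2)
    if (ss < best_ss) { best_ss <- ss; best <- thr }
  }
  best
}

# direct SSIM evaluation: per-pixel Gaussian-weighted window statistics
# with index clamping at borders (same boundary rule as the implementation,
# arrived at independently by explicit loops).
oracle_ssim <- function(a, b, window = 7, sigma = 1.5) {
  r <- (window - 1) %/% 2
  k <- exp(-((-r):r)^2 / (2 * sigma^2)); k <- k / sum(k)
  h <- nrow(a); w <- ncol(a)
  C1 <- (0.01 * 255)^2; C2 <- (0.03 * 255)^2
  total <- 0
  for (y in 1:h) for (x in 1:w) {
    wa <- wb <- waa <- wbb <- wab <- 0
    for (i in -r:r) for (j in -r:r) {
      yy <- min(max(y + i, 1), h); xx <- min(max(x + j, 1), w)
      wt <- k[i + r + 1] * k[j + r + 1]
      va <- a[yy, xx]; vb <- b[yy, xx]
      wa <- wa + wt * va; wb <- wb + wt * vb
      waa <- waa + wt * va * va; wbb <- wbb + wt * vb * vb
      wab <- wab + wt * va * vb
    }
    va <- waa - wa^2; vb <- wbb - wb^2; vab <- wab - wa * wb
    total <- total + ((2 * wa * wb + C1) * (2 * vab + C2)) /
      ((wa^2 + wb^2 + C1) * (va + vb + C2))
  }
  total / (h * w)
}
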