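# Small image helpers shared by tracking and dense flow.

# Pad a matrix by one pixel with reflected (mirror) borders.
pad_reflect1 <- function(m) {
  h <- nrow(m); w <- ncol(m)
  ri <- c(1L, seq_len(h), h)
  ci <- c(1L, seq_len(w), w)
  m[ri, ci, drop = FALSE]
}

# 3x3 convolution (correlation) with reflective border handling.
# `k` is a 3x3 kernel indexed k[dr+2, dc+2] for offsets dr, dc in {-1,0,1}.
conv3x3_reflect <- function(m, k) {
  h <- nrow(m); w <- ncol(m)
  p <- pad_reflect1(m)
  out <- matrix(0, h, w)
  for (dr in -1:1) for (dc in -1:1) {
    kk <- k[dr + 2L, dc + 2L]
    if (kk != 0)
      out <- out + kk * p[(2L + dr):(h + 1L + dr), (2L + dc):(w + 1L + dc)]
  }
  out
}

# Sobel kernels normalized by 1/8 so a unit intensity ramp has unit gradient.
# x = columns (increasing rightward), y = rows (increasing downward).
sobel_x_kernel <- function() matrix(c(-1, -2, -1, 0, 0, 0, 1, 2, 1), 3, 3) / 8
sobel_y_kernel <- function() t(sobel_x_kernel())

# Bilinear sampling of matrix `m` at fractional (row, col) positions.
# Positions are clamped to the valid domain.
bilinear_sample <- function(m, r, c) {
  h <- nrow(m); w <- ncol(m)
  r <- pmin(pmax(r, 1), h)
  c <- pmin(pmax(c, 1), w)
  r0 <- pmin(floor(r), h - 1L); c0 <- pmin(floor(c), w - 1L)
  fr <- r - r0; fc <- c - c0
  i00 <- (c0 - 1) * h + r0
  m[i00]          * (1 - fr) * (1 - fc) +
  m[i00 + 1]      * fr       * (1 - fc) +
  m[i00 + h]      * (1 - fr) * fc       +
  m[i00 + h + 1]  * fr       * fc
}

# Shift a matrix by a fractional (dr, dc) with bilinear interpolation,
# clamped sampling at the borders (content moves by +dr, +dc).
shift_bilinear <- function(m, dr, dc) {
  h <- nrow(m); w <- ncol(m)
  rr <- matrix(seq_len(h), h, w) - dr
  cc <- matrix(rep(seq_len(w), each = h), h, w) - dc
  matrix(bilinear_sample(m, rr, cc), h, w)
}

# Separable Gaussian blur with reflective borders; radius chosen as 3*sigma.
gauss_blur <- function(m, sigma) {
  if (sigma <= 0) return(m)
  r <- max(1L, ceiling(3 * sigma))
  x <- (-r):r
  k <- exp(-x^2 / (2 * sigma^2))
  k <- k / sum(k)
  h <- nrow(m); w <- ncol(m)
  ri <- pmin(pmax(outer(seq_len(h), x, `+`), 1L), h)
  out <- matrix(0, h, w)
  for (j in seq_along(x)) out <- out + k[j] * m[ri[, j], , drop = FALSE]
  ci <- pmin(pmax(outer(seq_len(w), x, `+`), 1L), w)
  out2 <- matrix(0, h, w)
  for (j in seq_along(x)) out2 <- out2 + k[j] * out[, ci[, j], drop = FALSE]
  out2
}

# Semi-Lagrangian advection under a spatially varying velocity field:
# each output pixel samples the input at its backtraced position.
advect_field <- function(m, vr, vc) {
  h <- nrow(m); w <- ncol(m)
  rr <- matrix(seq_len(h), h, w) - vr
  cc <- matrix(rep(seq_len(w), each = h), h, w) - vc
  matrix(bilinear_sample(m, rr, cc), h, w)
}

# Divergence-free (curl-noise) random velocity field with the given RMS
# speed and spatial correlation scale: the curl of a smoothed random
# potential.
curl_noise_field <- function(h, w, rms, scale = 8) {
  if (rms <= 0) return(list(vr = matrix(0, h, w), vc = matrix(0, h, w)))
  psi <- gauss_blur(matrix(stats::rnorm(h * w), h, w), scale)
  vr <- (psi[, c(2:w, w)] - psi[, c(1, 1:(w - 1))]) / 2    # d(psi)/dx
  vc <- -(psi[c(2:h, h), ] - psi[c(1, 1:(h - 1)), ]) / 2   # -d(psi)/dy
  sc <- rms / sqrt(mean(vr^2 + vc^2) + 1e-30)
  list(vr = vr * sc, vc = vc * sc)
}

# Binary dilation with a square structuring element of the given radius.
dilate_mask <- function(mask, radius) {
  if (radius <= 0) return(mask)
  h <- nrow(mask); w <- ncol(mask)
  out <- matrix(FALSE, h, w)
  for (dr in -radius:radius) {
    rs <- pmin(pmax(seq_len(h) + dr, 1L), h)
    for (dc in -radius:radius) {
      cs <- pmin(pmax(seq_len(w) + dc, 1L), w)
      out <- out | mask[rs, cs, drop = FALSE]
    }
  }
  out
}
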