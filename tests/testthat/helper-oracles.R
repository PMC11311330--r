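# Independent brute-force oracles used to validate the vectorized
# implementations. Everything here is deliberately naive: explicit loops,
# scalar arithmetic, reflective indexing done by hand.

reflect_idx <- function(i, n) min(max(i, 1L), n)

# Loop-based 3x3 Sobel (normalized by 1/8), reflective borders.
oracle_sobel <- function(m, direction = c("x", "y")) {
  direction <- match.arg(direction)
  kx <- matrix(c(-1, -2, -1, 0, 0, 0, 1, 2, 1), 3, 3) / 8  # k[dr+2, dc+2]
  h <- nrow(m); w <- ncol(m)
  out <- matrix(0, h, w)
  for (r in seq_len(h)) for (cl in seq_len(w)) {
    s <- 0
    for (dr in -1:1) for (dc in -1:1) {
      v <- m[reflect_idx(r + dr, h), reflect_idx(cl + dc, w)]
      s <- s + v * (if (direction == "x") kx[dr + 2L, dc + 2L]
                    else kx[dc + 2L, dr + 2L])
    }
    out[r, cl] <- s
  }
  out
}

# Loop-based Horn-Schunck iteration exactly as the printed update rule:
# neighbourhood average, then the coupled correction with denominator
# alpha + Ix^2 + Iy^2.
oracle_horn_schunck <- function(f1, f2, alpha, n_iter) {
  h <- nrow(f1); w <- ncol(f1)
  ix <- oracle_sobel(f1, "x")
  iy <- oracle_sobel(f1, "y")
  it <- f2 - f1
  avg1 <- function(m) {
    k <- matrix(c(1/12, 1/6, 1/12, 1/6, 0, 1/6, 1/12, 1/6, 1/12), 3, 3)
    out <- matrix(0, h, w)
    for (r in seq_len(h)) for (cl in seq_len(w)) {
      s <- 0
      for (dr in -1:1) for (dc in -1:1)
        s <- s + k[dr + 2L, dc + 2L] *
          m[reflect_idx(r + dr, h), reflect_idx(cl + dc, w)]
      out[r, cl] <- s
    }
    out
  }
  u <- matrix(0, h, w); v <- matrix(0, h, w)
  for (i in seq_len(n_iter)) {
    ub <- avg1(u); vb <- avg1(v)
    for (r in seq_len(h)) for (cl in seq_len(w)) {
      common <- (ix[r, cl] * ub[r, cl] + iy[r, cl] * vb[r, cl] + it[r, cl]) /
        (alpha + ix[r, cl]^2 + iy[r, cl]^2)
      u[r, cl] <- ub[r, cl] - ix[r, cl] * common
      v[r, cl] <- vb[r, cl] - iy[r, cl] * common
    }
  }
  array(c(u, v), dim = c(h, w, 2L))
}

# Exhaustive integer-shift SSD matching: the displacement of `cur` relative
# to `prev` restricted to a search radius.
oracle_ssd_shift <- function(prev, cur, radius = 5L) {
  h <- nrow(prev); w <- ncol(prev)
  best <- c(0L, 0L); best_ssd <- Inf
  for (dr in -radius:radius) for (dc in -radius:radius) {
    rs <- (1L + max(0L, dr)):(h + min(0L, dr))
    cs <- (1L + max(0L, dc)):(w + min(0L, dc))
    ssd <- mean((cur[rs, cs] - prev[rs - dr, cs - dc])^2)
    if (ssd < best_ssd) { best_ssd <- ssd; best <- c(dr, dc) }
  }
  best
}

# Naive double-loop magnitude sum.
oracle_reduce_field <- function(field) {
  s <- 0
  for (r in seq_len(dim(field)[1L])) for (cl in seq_len(dim(field)[2L]))
    s <- s + sqrt(field[r, cl, 1L]^2 + field[r, cl, 2L]^2)
  s
}

random_field <- function(h, w, scale = 1) {
  array(stats::rnorm(h * w * 2, sd = scale), dim = c(h, w, 2L))
}
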