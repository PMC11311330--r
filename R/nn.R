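# Minimal neural-network engine used by FieldNet and the 1-D exhale models.
#
# Design: single-sample forward/backward passes built on im2col gathers and
# BLAS matrix products, gradients accumulated over a mini-batch, Adam
# updates on a flat named list of parameter arrays. Everything is plain R;
# determinism follows from seeded initialization and seeded batch order.

## ---- parameter initialization -------------------------------------------

glorot_uniform <- function(nrow, ncol, fan_in = nrow, fan_out = ncol) {
  lim <- sqrt(6 / (fan_in + fan_out))
  matrix(stats::runif(nrow * ncol, -lim, lim), nrow, ncol)
}

## ---- Adam ----------------------------------------------------------------

adam_init <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0),
       t = 0L)
}

adam_step <- function(params, grads, state, lr = 1e-3, beta1 = 0.9,
                      beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(params)) {
    g <- grads[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g * g
    params[[nm]] <- params[[nm]] -
      lr * (state$m[[nm]] / bc1) / (sqrt(state$v[[nm]] / bc2) + eps)
  }
  list(params = params, state = state)
}

## ---- 2-D convolution (3x3 same, zero padding) ---------------------------

# Cached gather index turning a zero-padded (h+2, w+2, C) array into the
# (h*w, 9*C) im2col patch matrix.
.im2col_cache <- new.env(parent = emptyenv())

im2col3_index <- function(h, w, C) {
  key <- paste(h, w, C, sep = "x")
  if (!is.null(.im2col_cache[[key]])) return(.im2col_cache[[key]])
  hp <- h + 2L; wp <- w + 2L
  rows <- rep(seq_len(h), times = w)       # output pixel rows
  cols <- rep(seq_len(w), each = h)        # output pixel cols
  idx <- integer(h * w * 9L * C)
  pos <- 1L
  for (ki in 0:8) {                        # kernel offset, column-major 3x3
    dr <- ki %% 3L                          # 0,1,2 -> row offset in padded
    dc <- ki %/% 3L
    for (ch in seq_len(C)) {
      base <- (ch - 1L) * hp * wp
      idx[pos:(pos + h * w - 1L)] <- base + (cols + dc - 1L) * hp + (rows + dr)
      pos <- pos + h * w
    }
  }
  .im2col_cache[[key]] <- idx
  idx
}

pad_zero2 <- function(x) {
  d <- dim(x)
  xp <- array(0, dim = c(d[1L] + 2L, d[2L] + 2L, d[3L]))
  xp[2:(d[1L] + 1L), 2:(d[2L] + 1L), ] <- x
  xp
}

# x: (h, w, Cin); W: (9*Cin, Cout); b: length Cout
conv2d3_fwd <- function(x, W, b) {
  d <- dim(x)
  idx <- im2col3_index(d[1L], d[2L], d[3L])
  patches <- pad_zero2(x)[idx]
  dim(patches) <- c(d[1L] * d[2L], 9L * d[3L])
  y <- patches %*% W
  y <- y + rep(b, each = nrow(y))
  dim(y) <- c(d[1L], d[2L], ncol(W))
  list(y = y, patches = patches, dims = d)
}

# Rearrange W (9*Cin, Cout) into the adjoint kernel (9*Cout, Cin): the
# spatially flipped, channel-transposed weights, so dx is itself a 3x3
# convolution of dy and the backward pass reuses the fast im2col path.
conv2d3_flip_W <- function(W, cin) {
  cout <- ncol(W)
  dim(W) <- c(cin, 9L, cout)
  Wb <- aperm(W[, 9:1, , drop = FALSE], c(3L, 2L, 1L))  # (cout, 9, cin)
  dim(Wb) <- c(9L * cout, cin)
  Wb
}

conv2d3_bwd <- function(dy, cache, W) {
  d <- cache$dims
  cout <- dim(dy)[3L]
  dym <- dy
  dim(dym) <- c(d[1L] * d[2L], cout)
  dW <- crossprod(cache$patches, dym)
  db <- colSums(dym)
  idx <- im2col3_index(d[1L], d[2L], cout)
  dyp <- pad_zero2(dy)[idx]
  dim(dyp) <- c(d[1L] * d[2L], 9L * cout)
  dx <- dyp %*% conv2d3_flip_W(W, d[3L])
  dim(dx) <- d
  list(dx = dx, dW = dW, db = db)
}

# 1x1 convolution: a per-pixel linear map.
conv2d1_fwd <- function(x, W, b) {
  d <- dim(x)
  xm <- matrix(x, d[1L] * d[2L], d[3L])
  y <- sweep(xm %*% W, 2L, b, `+`)
  list(y = array(y, dim = c(d[1L], d[2L], ncol(W))), xm = xm, dims = d)
}

conv2d1_bwd <- function(dy, cache, W) {
  d <- cache$dims
  dym <- matrix(dy, d[1L] * d[2L], dim(dy)[3L])
  list(dx = array(dym %*% t(W), dim = d),
       dW = crossprod(cache$xm, dym), db = colSums(dym))
}

## ---- pooling / upsampling / activations ---------------------------------

maxpool2_fwd <- function(x) {
  d <- dim(x)
  h2 <- d[1L] %/% 2L; w2 <- d[2L] %/% 2L
  a <- x[seq(1L, 2L * h2, 2L), seq(1L, 2L * w2, 2L), , drop = FALSE]
  b <- x[seq(2L, 2L * h2, 2L), seq(1L, 2L * w2, 2L), , drop = FALSE]
  cc <- x[seq(1L, 2L * h2, 2L), seq(2L, 2L * w2, 2L), , drop = FALSE]
  dd <- x[seq(2L, 2L * h2, 2L), seq(2L, 2L * w2, 2L), , drop = FALSE]
  y <- pmax(a, b, cc, dd)
  which4 <- 1L * (y == a)
  which4[which4 == 0 & y == b] <- 2L
  which4[which4 == 0 & y == cc] <- 3L
  which4[which4 == 0 & y == dd] <- 4L
  list(y = y, which4 = which4, dims = d)
}

maxpool2_bwd <- function(dy, cache) {
  d <- cache$dims
  h2 <- d[1L] %/% 2L; w2 <- d[2L] %/% 2L
  dx <- array(0, dim = d)
  w4 <- cache$which4
  ro <- list(seq(1L, 2L * h2, 2L), seq(2L, 2L * h2, 2L),
             seq(1L, 2L * h2, 2L), seq(2L, 2L * h2, 2L))
  co <- list(seq(1L, 2L * w2, 2L), seq(1L, 2L * w2, 2L),
             seq(2L, 2L * w2, 2L), seq(2L, 2L * w2, 2L))
  for (k in 1:4) {
    g <- dy * (w4 == k)
    dx[ro[[k]], co[[k]], ] <- dx[ro[[k]], co[[k]], ] + g
  }
  dx
}

upsample2_fwd <- function(x) {
  d <- dim(x)
  ri <- rep(seq_len(d[1L]), each = 2L)
  ci <- rep(seq_len(d[2L]), each = 2L)
  list(y = x[ri, ci, , drop = FALSE], dims = d)
}

upsample2_bwd <- function(dy, cache) {
  d <- cache$dims
  a <- dy[seq(1L, 2L * d[1L], 2L), seq(1L, 2L * d[2L], 2L), , drop = FALSE]
  b <- dy[seq(2L, 2L * d[1L], 2L), seq(1L, 2L * d[2L], 2L), , drop = FALSE]
  cc <- dy[seq(1L, 2L * d[1L], 2L), seq(2L, 2L * d[2L], 2L), , drop = FALSE]
  dd <- dy[seq(2L, 2L * d[1L], 2L), seq(2L, 2L * d[2L], 2L), , drop = FALSE]
  a + b + cc + dd
}

tanh_fwd <- function(x) tanh(x)
tanh_bwd <- function(dy, y) dy * (1 - y * y)
relu_fwd <- function(x) pmax(x, 0)
relu_bwd <- function(dy, y) dy * (y > 0)

dropout_fwd <- function(x, rate, training) {
  if (!training || rate <= 0) return(list(y = x, mask = NULL))
  mask <- (array(stats::runif(length(x)), dim = dim(x)) >= rate) / (1 - rate)
  list(y = x * mask, mask = mask)
}

dropout_bwd <- function(dy, mask) if (is.null(mask)) dy else dy * mask

## ---- 1-D convolution -----------------------------------------------------

# x: (L, Cin); W: (k*Cin, Cout); 'same'-style zero padding p = (k-1)/2,
# stride s; Lout = floor((L + 2p - k)/s) + 1.
conv1d_fwd <- function(x, W, b, k, stride = 1L) {
  L <- nrow(x); cin <- ncol(x)
  p <- (k - 1L) %/% 2L
  xp <- rbind(matrix(0, p, cin), x, matrix(0, p, cin))
  lout <- (L + 2L * p - k) %/% stride + 1L
  starts <- (seq_len(lout) - 1L) * stride
  patches <- matrix(0, lout, k * cin)
  for (j in seq_len(k))
    patches[, ((j - 1L) * cin + 1L):(j * cin)] <- xp[starts + j, , drop = FALSE]
  y <- sweep(patches %*% W, 2L, b, `+`)
  list(y = y, patches = patches, L = L, cin = cin, k = k, stride = stride,
       p = p, starts = starts)
}

conv1d_bwd <- function(dy, cache, W) {
  dW <- crossprod(cache$patches, dy)
  db <- colSums(dy)
  dpatch <- dy %*% t(W)
  cin <- cache$cin; k <- cache$k; p <- cache$p
  dxp <- matrix(0, cache$L + 2L * p, cin)
  for (j in seq_len(k)) {
    rows <- cache$starts + j
    dxp[rows, ] <- dxp[rows, ] +
      dpatch[, ((j - 1L) * cin + 1L):(j * cin), drop = FALSE]
  }
  list(dx = dxp[(p + 1L):(p + cache$L), , drop = FALSE], dW = dW, db = db)
}

# Transposed 1-D convolution with stride 2 as zero-insertion upsampling
# followed by a stride-1 convolution; output length is 2L.
conv1d_transpose_fwd <- function(x, W, b, k) {
  L <- nrow(x); cin <- ncol(x)
  up <- matrix(0, 2L * L, cin)
  up[seq(1L, 2L * L, 2L), ] <- x
  cv <- conv1d_fwd(up, W, b, k, stride = 1L)
  c(cv, list(Lin = L))
}

conv1d_transpose_bwd <- function(dy, cache, W) {
  g <- conv1d_bwd(dy, cache, W)
  list(dx = g$dx[seq(1L, 2L * cache$Lin, 2L), , drop = FALSE],
       dW = g$dW, db = g$db)
}

## ---- generic sequential 1-D network -------------------------------------

# Layer spec: list(cin, cout, k, stride, transpose, act) with act in
# {"relu", "linear"}. Parameters are named W1/b1, W2/b2, ...
conv1d_net_init <- function(layers, seed) {
  with_seed(seed, {
    params <- list()
    for (i in seq_along(layers)) {
      ly <- layers[[i]]
      params[[paste0("W", i)]] <-
        glorot_uniform(ly$k * ly$cin, ly$cout,
                       fan_in = ly$k * ly$cin, fan_out = ly$k * ly$cout)
      params[[paste0("b", i)]] <- numeric(ly$cout)
    }
    params
  })
}

conv1d_net_fwd <- function(x, layers, params, keep_cache = FALSE) {
  caches <- vector("list", length(layers))
  for (i in seq_along(layers)) {
    ly <- layers[[i]]
    W <- params[[paste0("W", i)]]; b <- params[[paste0("b", i)]]
    cv <- if (isTRUE(ly$transpose)) conv1d_transpose_fwd(x, W, b, ly$k)
          else conv1d_fwd(x, W, b, ly$k, ly$stride)
    y <- if (ly$act == "relu") relu_fwd(cv$y) else cv$y
    if (keep_cache) caches[[i]] <- list(cv = cv, y = y)
    x <- y
  }
  if (keep_cache) list(y = x, caches = caches) else list(y = x)
}

conv1d_net_bwd <- function(dy, layers, params, caches) {
  grads <- list()
  for (i in rev(seq_along(layers))) {
    ly <- layers[[i]]
    W <- params[[paste0("W", i)]]
    cc <- caches[[i]]
    if (ly$act == "relu") dy <- relu_bwd(dy, cc$y)
    g <- if (isTRUE(ly$transpose)) conv1d_transpose_bwd(dy, cc$cv, W)
         else conv1d_bwd(dy, cc$cv, W)
    grads[[paste0("W", i)]] <- g$dW
    grads[[paste0("b", i)]] <- g$db
    dy <- g$dx
  }
  grads
}

# Shared mini-batch training loop for the 1-D networks. xs/ys: lists of
# (L, C) matrices. Returns params, adam state and per-epoch mean MSE.
conv1d_net_train <- function(layers, params, xs, ys, epochs, batch_size,
                             lr, seed) {
  state <- adam_init(params)
  history <- numeric(epochs)
  n <- length(xs)
  for (ep in seq_len(epochs)) {
    ord <- with_seed(seed + ep, sample.int(n))
    ep_loss <- 0
    for (start in seq(1L, n, by = batch_size)) {
      bidx <- ord[start:min(start + batch_size - 1L, n)]
      grads <- NULL
      bloss <- 0
      for (s in bidx) {
        fw <- conv1d_net_fwd(xs[[s]], layers, params, keep_cache = TRUE)
        err <- fw$y - ys[[s]]
        bloss <- bloss + mean(err^2)
        dy <- 2 * err / length(err)
        g <- conv1d_net_bwd(dy, layers, params, fw$caches)
        grads <- if (is.null(grads)) g
                 else Map(`+`, grads, g[names(grads)])
      }
      grads <- lapply(grads, `/`, length(bidx))
      up <- adam_step(params, grads, state, lr = lr)
      params <- up$params; state <- up$state
      ep_loss <- ep_loss + bloss
    }
    history[ep] <- ep_loss / n
  }
  list(params = params, state = state, history = history)
}
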