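#' FieldNet configuration
#'
#' U-Net style encoder-decoder for flow-field interpolation. The input
#' stacks two encoded fields, `(h, w, 4)`; the output is the predicted
#' intermediate encoded field `(h, w, 2)`. Channel widths follow the usual
#' doubling `(base, 2*base, 4*base)` across the two encoder levels and the
#' bottleneck; skip connections concatenate each encoder level into the
#' decoder. All layers use tanh, matching the `[-1, 1]` encoding.
#'
#' The desk-scale default (`h = w = 64`, `base_channels = 16`) is used for
#' training and tests; `fieldnet_reference_config()` pins the full-size
#' reference width.
#'
#' @param height,width field size; both must be divisible by 4 (two 2x2
#'   pooling levels).
#' @param base_channels width of the first encoder level (default 16).
#' @param dropout dropout rate after each encoder block (default 0.025).
#' @param learning_rate Adam learning rate (default 1e-3).
#' @param batch_size mini-batch size (default 64).
#' @param epochs training epochs (default 16).
#' @param seed integer seed for initialization and batch order.
#' @return An object of class `fieldnet_config`.
#' @export
fieldnet_config <- function(height = 64, width = 64, base_channels = 16,
                            dropout = 0.025, learning_rate = 1e-3,
                            batch_size = 64, epochs = 16, seed = 1) {
  if (height %% 4 != 0 || width %% 4 != 0)
    stop("height and width must be divisible by 4")
  if (dropout < 0 || dropout >= 1) stop("dropout must be in [0, 1)")
  structure(list(height = as.integer(height), width = as.integer(width),
                 base_channels = as.integer(base_channels),
                 dropout = dropout, learning_rate = learning_rate,
                 batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs), seed = as.integer(seed)),
            class = "fieldnet_config")
}

#' Reference (full-size) FieldNet configuration
#'
#' The full-size architecture targets 18.7 million trainable parameters;
#' with the doubling scheme used here a base width of 202 channels realises
#' that count (18,740,754 parameters). Used for the parameter-count check
#' only; training runs use the desk-scale default.
#'
#' @return A [fieldnet_config()] with `base_channels = 202`.
#' @export
fieldnet_reference_config <- function() {
  fieldnet_config(height = 64, width = 64, base_channels = 202)
}

fieldnet_layer_dims <- function(config) {
  c1 <- config$base_channels; c2 <- 2L * c1; cb <- 4L * c1
  list(
    e1a = c(4L, c1),       e1b = c(c1, c1),
    e2a = c(c1, c2),       e2b = c(c2, c2),
    ba  = c(c2, cb),       bb  = c(cb, cb),
    d2a = c(cb + c2, c2),  d2b = c(c2, c2),
    d1a = c(c2 + c1, c1),  d1b = c(c1, c1),
    out = c(c1, 2L)
  )
}

#' Build an (untrained) FieldNet
#'
#' Structure: two encoder blocks (conv3x3-tanh, conv3x3-tanh, maxpool,
#' dropout), a bottleneck (conv3x3-tanh x2), two decoder blocks (nearest
#' upsample, skip concatenation, conv3x3-tanh x2) and a final 1x1 conv with
#' tanh to 2 channels. Weights are Glorot-uniform, seeded from the config.
#'
#' @param config a [fieldnet_config()].
#' @return An object of class `fieldnet` with elements `params`, `config`,
#'   `history` (per-epoch train/val MSE, initially empty).
#' @export
build_fieldnet <- function(config = fieldnet_config()) {
  dims <- fieldnet_layer_dims(config)
  params <- with_seed(config$seed, {
    p <- list()
    for (nm in names(dims)) {
      cin <- dims[[nm]][1L]; cout <- dims[[nm]][2L]
      kk <- if (nm == "out") 1L else 9L
      p[[paste0(nm, "_W")]] <- glorot_uniform(kk * cin, cout,
                                              fan_in = kk * cin,
                                              fan_out = kk * cout)
      p[[paste0(nm, "_b")]] <- numeric(cout)
    }
    p
  })
  structure(list(params = params, config = config,
                 history = data.frame(epoch = integer(), train_mse = numeric(),
                                      val_mse = numeric())),
            class = "fieldnet")
}

#' Number of trainable parameters of a FieldNet
#'
#' @param model a `fieldnet` object (or a [fieldnet_config()]).
#' @return integer parameter count (weights + biases).
#' @export
fieldnet_num_params <- function(model) {
  params <- if (inherits(model, "fieldnet")) model$params
            else build_fieldnet(model)$params
  sum(vapply(params, length, numeric(1)))
}

#' @export
print.fieldnet <- function(x, ...) {
  cfg <- x$config
  cat(sprintf("<fieldnet> %dx%d input, base %d channels, %s parameters\n",
              cfg$height, cfg$width, cfg$base_channels,
              format(fieldnet_num_params(x), big.mark = ",")))
  if (nrow(x$history) > 0)
    cat(sprintf("  trained %d epochs; final train/val MSE %.3g / %.3g\n",
                nrow(x$history), utils::tail(x$history$train_mse, 1),
                utils::tail(x$history$val_mse, 1)))
  else cat("  untrained\n")
  invisible(x)
}

# Full forward pass; training = TRUE keeps every cache for backprop and
# samples dropout masks (inference is deterministic: dropout disabled).
fieldnet_fwd <- function(params, x, dropout = 0, training = FALSE) {
  cache <- list()
  cv <- conv2d3_fwd(x, params$e1a_W, params$e1a_b); a1 <- tanh_fwd(cv$y)
  cache$e1a <- cv; cache$a1 <- a1
  cv <- conv2d3_fwd(a1, params$e1b_W, params$e1b_b); s1 <- tanh_fwd(cv$y)
  cache$e1b <- cv; cache$s1 <- s1
  mp <- maxpool2_fwd(s1); cache$p1 <- mp
  dp <- dropout_fwd(mp$y, dropout, training); cache$do1 <- dp
  cv <- conv2d3_fwd(dp$y, params$e2a_W, params$e2a_b); a3 <- tanh_fwd(cv$y)
  cache$e2a <- cv; cache$a3 <- a3
  cv <- conv2d3_fwd(a3, params$e2b_W, params$e2b_b); s2 <- tanh_fwd(cv$y)
  cache$e2b <- cv; cache$s2 <- s2
  mp <- maxpool2_fwd(s2); cache$p2 <- mp
  dp <- dropout_fwd(mp$y, dropout, training); cache$do2 <- dp
  cv <- conv2d3_fwd(dp$y, params$ba_W, params$ba_b); b1 <- tanh_fwd(cv$y)
  cache$ba <- cv; cache$b1 <- b1
  cv <- conv2d3_fwd(b1, params$bb_W, params$bb_b); b2 <- tanh_fwd(cv$y)
  cache$bb <- cv; cache$b2 <- b2
  up <- upsample2_fwd(b2); cache$u2 <- up
  cat2 <- array(c(up$y, s2), dim = c(dim(up$y)[1:2], dim(up$y)[3L] + dim(s2)[3L]))
  cv <- conv2d3_fwd(cat2, params$d2a_W, params$d2a_b); a5 <- tanh_fwd(cv$y)
  cache$d2a <- cv; cache$a5 <- a5
  cv <- conv2d3_fwd(a5, params$d2b_W, params$d2b_b); a6 <- tanh_fwd(cv$y)
  cache$d2b <- cv; cache$a6 <- a6
  up <- upsample2_fwd(a6); cache$u1 <- up
  cat1 <- array(c(up$y, s1), dim = c(dim(up$y)[1:2], dim(up$y)[3L] + dim(s1)[3L]))
  cv <- conv2d3_fwd(cat1, params$d1a_W, params$d1a_b); a7 <- tanh_fwd(cv$y)
  cache$d1a <- cv; cache$a7 <- a7
  cv <- conv2d3_fwd(a7, params$d1b_W, params$d1b_b); a8 <- tanh_fwd(cv$y)
  cache$d1b <- cv; cache$a8 <- a8
  cv <- conv2d1_fwd(a8, params$out_W, params$out_b); y <- tanh_fwd(cv$y)
  cache$out <- cv; cache$y <- y
  if (training) list(y = y, cache = cache) else list(y = y)
}

fieldnet_bwd <- function(params, cache, dy) {
  g <- list()
  dy <- tanh_bwd(dy, cache$y)
  bw <- conv2d1_bwd(dy, cache$out, params$out_W)
  g$out_W <- bw$dW; g$out_b <- bw$db
  dy <- tanh_bwd(bw$dx, cache$a8)
  bw <- conv2d3_bwd(dy, cache$d1b, params$d1b_W)
  g$d1b_W <- bw$dW; g$d1b_b <- bw$db
  dy <- tanh_bwd(bw$dx, cache$a7)
  bw <- conv2d3_bwd(dy, cache$d1a, params$d1a_W)
  g$d1a_W <- bw$dW; g$d1a_b <- bw$db
  # split concat(u1, s1)
  cu <- dim(cache$u1$y)[3L]
  d_u1 <- bw$dx[, , seq_len(cu), drop = FALSE]
  d_s1_skip <- bw$dx[, , (cu + 1L):dim(bw$dx)[3L], drop = FALSE]
  dy <- upsample2_bwd(d_u1, cache$u1)
  dy <- tanh_bwd(dy, cache$a6)
  bw <- conv2d3_bwd(dy, cache$d2b, params$d2b_W)
  g$d2b_W <- bw$dW; g$d2b_b <- bw$db
  dy <- tanh_bwd(bw$dx, cache$a5)
  bw <- conv2d3_bwd(dy, cache$d2a, params$d2a_W)
  g$d2a_W <- bw$dW; g$d2a_b <- bw$db
  cu <- dim(cache$u2$y)[3L]
  d_u2 <- bw$dx[, , seq_len(cu), drop = FALSE]
  d_s2_skip <- bw$dx[, , (cu + 1L):dim(bw$dx)[3L], drop = FALSE]
  dy <- upsample2_bwd(d_u2, cache$u2)
  dy <- tanh_bwd(dy, cache$b2)
  bw <- conv2d3_bwd(dy, cache$bb, params$bb_W)
  g$bb_W <- bw$dW; g$bb_b <- bw$db
  dy <- tanh_bwd(bw$dx, cache$b1)
  bw <- conv2d3_bwd(dy, cache$ba, params$ba_W)
  g$ba_W <- bw$dW; g$ba_b <- bw$db
  dy <- dropout_bwd(bw$dx, cache$do2$mask)
  dy <- maxpool2_bwd(dy, cache$p2)
  dy <- dy + d_s2_skip                       # skip gradient joins here
  dy <- tanh_bwd(dy, cache$s2)
  bw <- conv2d3_bwd(dy, cache$e2b, params$e2b_W)
  g$e2b_W <- bw$dW; g$e2b_b <- bw$db
  dy <- tanh_bwd(bw$dx, cache$a3)
  bw <- conv2d3_bwd(dy, cache$e2a, params$e2a_W)
  g$e2a_W <- bw$dW; g$e2a_b <- bw$db
  dy <- dropout_bwd(bw$dx, cache$do1$mask)
  dy <- maxpool2_bwd(dy, cache$p1)
  dy <- dy + d_s1_skip
  dy <- tanh_bwd(dy, cache$s1)
  bw <- conv2d3_bwd(dy, cache$e1b, params$e1b_W)
  g$e1b_W <- bw$dW; g$e1b_b <- bw$db
  dy <- tanh_bwd(bw$dx, cache$a1)
  bw <- conv2d3_bwd(dy, cache$e1a, params$e1a_W)
  g$e1a_W <- bw$dW; g$e1a_b <- bw$db
  g
}

fieldnet_dataset_mse <- function(params, ds) {
  if (length(ds) == 0L) return(NA_real_)
  tot <- 0
  for (i in seq_along(ds$x)) {
    y <- fieldnet_fwd(params, ds$x[[i]])$y
    tot <- tot + mean((y - ds$y[[i]])^2)
  }
  tot / length(ds$x)
}

#' Train FieldNet
#'
#' MSE loss, Adam at the configured learning rate, seeded shuffled
#' mini-batches. The per-epoch training loss (running mean over batches) and
#' validation MSE are recorded in `model$history`.
#'
#' @param model a `fieldnet` from [build_fieldnet()].
#' @param train,val [interleaved_dataset()]s (val may be empty for no
#'   monitoring).
#' @param epochs optional override of `config$epochs`.
#' @param verbose print per-epoch losses.
#' @return the trained `fieldnet`.
#' @export
train_fieldnet <- function(model, train, val = NULL, epochs = NULL,
                           verbose = FALSE) {
  stopifnot(inherits(model, "fieldnet"), inherits(train, "interleaved_dataset"))
  if (length(train) == 0L) stop("empty training dataset")
  cfg <- model$config
  d <- dim(train$x[[1L]])
  if (d[1L] != cfg$height || d[2L] != cfg$width || d[3L] != 4L)
    stop("dataset shape does not match config")
  epochs <- if (is.null(epochs)) cfg$epochs else as.integer(epochs)
  params <- model$params
  state <- adam_init(params)
  n <- length(train)
  hist <- model$history
  n_steps <- epochs * ceiling(n / cfg$batch_size)
  step <- 0L
  for (ep in seq_len(epochs)) {
    ord <- with_seed(cfg$seed + 1000L + ep, sample.int(n))
    masks_seed <- cfg$seed + 2000L + ep
    ep_loss <- 0
    bi <- 0L
    for (start in seq(1L, n, by = cfg$batch_size)) {
      bidx <- ord[start:min(start + cfg$batch_size - 1L, n)]
      bi <- bi + 1L
      grads <- NULL
      bloss <- 0
      set.seed(masks_seed + bi)  # dropout masks for this batch
      for (s in bidx) {
        fw <- fieldnet_fwd(params, train$x[[s]], dropout = cfg$dropout,
                           training = TRUE)
        err <- fw$y - train$y[[s]]
        bloss <- bloss + mean(err^2)
        dy <- 2 * err / length(err)
        g <- fieldnet_bwd(params, fw$cache, dy)
        grads <- if (is.null(grads)) g else Map(`+`, grads, g[names(grads)])
      }
      grads <- lapply(grads, `/`, length(bidx))
      # linear decay to 10% of the base rate over the run: the final
      # batches settle the weights instead of oscillating
      step <- step + 1L
      lr_t <- cfg$learning_rate * (1 - 0.9 * (step - 1L) / max(n_steps - 1L, 1L))
      up <- adam_step(params, grads, state, lr = lr_t)
      params <- up$params; state <- up$state
      ep_loss <- ep_loss + bloss
    }
    vmse <- if (!is.null(val)) fieldnet_dataset_mse(params, val) else NA_real_
    hist <- rbind(hist, data.frame(epoch = nrow(hist) + 1L,
                                   train_mse = ep_loss / n, val_mse = vmse))
    if (verbose)
      message(sprintf("epoch %d: train %.5f, val %.5f", ep, ep_loss / n, vmse))
  }
  model$params <- params
  model$history <- hist
  model
}

#' Predict the intermediate encoded field
#'
#' Given the encoded fields at t and t+2, returns the model's prediction of
#' the encoded field at t+1. Inference is deterministic (dropout disabled);
#' the output inherits the mean of the two inputs' normalization constants
#' so it can be decoded on the same magnitude scale.
#'
#' @param model a trained `fieldnet`.
#' @param f_t,f_t2 [encoded_field()]s of the configured size.
#' @return An [encoded_field()] prediction.
#' @export
predict_intermediate <- function(model, f_t, f_t2) {
  stopifnot(inherits(model, "fieldnet"),
            inherits(f_t, "encoded_field"), inherits(f_t2, "encoded_field"))
  cfg <- model$config
  d <- dim(f_t$data)
  if (d[1L] != cfg$height || d[2L] != cfg$width)
    stop("field shape does not match config")
  x <- array(c(f_t$data, f_t2$data), dim = c(d[1:2], 4L))
  y <- fieldnet_fwd(model$params, x)$y
  encoded_field(y, (f_t$n_max + f_t2$n_max) / 2)
}

#' Interpolation over a full encoded sequence
#'
#' Runs [predict_intermediate()] on every (t-1, t+1) pair, producing a
#' predicted field for each interior time step.
#'
#' @param model a trained `fieldnet`.
#' @param encoded list of [encoded_field()]s (length n >= 3).
#' @return list of n-2 predicted [encoded_field()]s, aligned with times
#'   2..n-1 of the input list.
#' @export
predict_sequence <- function(model, encoded) {
  n <- length(encoded)
  if (n < 3L) stop("need at least 3 encoded fields")
  out <- vector("list", n - 2L)
  for (t in 2:(n - 1L))
    out[[t - 1L]] <- predict_intermediate(model, encoded[[t - 1L]],
                                          encoded[[t + 1L]])
  out
}
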