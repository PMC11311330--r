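segment_matrix <- function(seg) {
  v <- if (inherits(seg, "exhale_segment")) seg$values else as.numeric(seg)
  if (length(v) != 256L) stop("segments must have length 256")
  matrix(v, ncol = 1L)
}

#' Train the 1-D denoising autoencoder
#'
#' Four convolutional layers with relu activation and kernel size 7: two
#' stride-2 encoder convolutions (widths 16 and 32, latent length 64) and
#' two stride-2 transposed decoder convolutions back to `(256, 1)`. The
#' target equals the input (identity training), so the bottleneck learns the
#' smooth exhale shape and discards turbulent per-sample variance. Adam,
#' learning rate 1e-3, MSE loss.
#'
#' @param segments non-empty list of [exhale_segment()]s (or length-256
#'   vectors).
#' @param seed integer seed.
#' @param epochs training epochs (default 50).
#' @param batch_size mini-batch size (default 16).
#' @return An object of class `exhale_denoiser` with a per-epoch MSE
#'   `history`.
#' @export
train_autoencoder <- function(segments, seed = 1, epochs = 50,
                              batch_size = 16) {
  if (length(segments) == 0L) stop("need at least one segment")
  xs <- lapply(segments, segment_matrix)
  layers <- list(
    list(cin = 1L, cout = 16L, k = 7L, stride = 2L, transpose = FALSE, act = "relu"),
    list(cin = 16L, cout = 32L, k = 7L, stride = 2L, transpose = FALSE, act = "relu"),
    list(cin = 32L, cout = 16L, k = 7L, stride = 2L, transpose = TRUE, act = "relu"),
    list(cin = 16L, cout = 1L, k = 7L, stride = 2L, transpose = TRUE, act = "relu")
  )
  params <- conv1d_net_init(layers, seed)
  tr <- conv1d_net_train(layers, params, xs, xs, epochs = epochs,
                         batch_size = batch_size, lr = 1e-3, seed = seed)
  structure(list(layers = layers, params = tr$params, history = tr$history,
                 seed = seed),
            class = "exhale_denoiser")
}

#' @export
print.exhale_denoiser <- function(x, ...) {
  cat(sprintf("<exhale_denoiser> conv1d autoencoder (k=7, latent 32x64), %d epochs, final MSE %.3g\n",
              length(x$history), utils::tail(x$history, 1)))
  invisible(x)
}

#' Denoise an exhale segment
#'
#' @param object an `exhale_denoiser`.
#' @param segment an [exhale_segment()] or length-256 vector.
#' @param ... unused.
#' @return the reconstructed [exhale_segment()].
#' @export
predict.exhale_denoiser <- function(object, segment, ...) {
  x <- segment_matrix(segment)
  y <- conv1d_net_fwd(x, object$layers, object$params)$y
  sb <- if (inherits(segment, "exhale_segment")) segment$source_bounds
        else c(NA_integer_, NA_integer_)
  exhale_segment(pmin(pmax(as.numeric(y), 0), 1), sb)
}

#' Anomaly training pairs from reference and input segments
#'
#' Full cross product of a reference set (idealized, regular exhales) with a
#' mixed input set: one pair per (ref, input) combination, so `n` references
#' and `m` inputs give exactly `n * m` pairs. Each target is the elementwise
#' anomaly error waveform `e(t) = |ref(t) - input(t)|`, which is symmetric
#' in its two arguments, nonnegative, and identically zero only for
#' identical segments.
#'
#' @param refs,inputs non-empty lists of [exhale_segment()]s (length 256).
#' @return list of pairs, each `list(x, y, ref_id, input_id)` with `x` the
#'   input segment values and `y` the error waveform (both length 256).
#' @export
build_anomaly_training_set <- function(refs, inputs) {
  if (length(refs) == 0L || length(inputs) == 0L)
    stop("refs and inputs must be non-empty")
  rmat <- lapply(refs, segment_matrix)
  imat <- lapply(inputs, segment_matrix)
  pairs <- vector("list", length(refs) * length(inputs))
  k <- 0L
  for (i in seq_along(rmat)) {
    for (j in seq_along(imat)) {
      k <- k + 1L
      pairs[[k]] <- list(x = as.numeric(imat[[j]]),
                         y = as.numeric(abs(rmat[[i]] - imat[[j]])),
                         ref_id = i, input_id = j)
    }
  }
  pairs
}

#' Train the anomaly scoring model
#'
#' Three 1-D convolutional layers (kernel size 7, widths 32-32-1, relu)
#' mapping a `(256, 1)` input segment to its predicted anomaly error
#' waveform. Supervised on [build_anomaly_training_set()] pairs with MSE
#' loss and Adam at learning rate 1e-3.
#'
#' @param pairs non-empty list from [build_anomaly_training_set()].
#' @param seed integer seed.
#' @param epochs training epochs (default 50).
#' @param batch_size mini-batch size (default 64).
#' @return An object of class `anomaly_scorer` with per-epoch MSE `history`.
#' @export
train_anomaly_model <- function(pairs, seed = 1, epochs = 50,
                                batch_size = 64) {
  if (length(pairs) == 0L) stop("need at least one training pair")
  xs <- lapply(pairs, function(p) matrix(p$x, ncol = 1L))
  ys <- lapply(pairs, function(p) matrix(p$y, ncol = 1L))
  layers <- list(
    list(cin = 1L, cout = 32L, k = 7L, stride = 1L, transpose = FALSE, act = "relu"),
    list(cin = 32L, cout = 32L, k = 7L, stride = 1L, transpose = FALSE, act = "relu"),
    list(cin = 32L, cout = 1L, k = 7L, stride = 1L, transpose = FALSE, act = "relu")
  )
  params <- conv1d_net_init(layers, seed)
  tr <- conv1d_net_train(layers, params, xs, ys, epochs = epochs,
                         batch_size = batch_size, lr = 1e-3, seed = seed)
  structure(list(layers = layers, params = tr$params, history = tr$history,
                 seed = seed),
            class = "anomaly_scorer")
}

#' @export
print.anomaly_scorer <- function(x, ...) {
  cat(sprintf("<anomaly_scorer> conv1d k=7 widths 32-32-1, %d epochs, final MSE %.3g\n",
              length(x$history), utils::tail(x$history, 1)))
  invisible(x)
}

#' Score an exhale segment against the reference model
#'
#' Deterministic at inference: the predicted error waveform is clamped to be
#' nonnegative and summarized by its mean (and maximum).
#'
#' @param model a trained `anomaly_scorer`.
#' @param segment an [exhale_segment()] or length-256 vector.
#' @return list of class `anomaly_score` with `error_waveform` (length 256),
#'   `summary` (mean predicted error) and `max_error`.
#' @export
score_segment <- function(model, segment) {
  stopifnot(inherits(model, "anomaly_scorer"))
  x <- segment_matrix(segment)
  e <- pmax(as.numeric(conv1d_net_fwd(x, model$layers, model$params)$y), 0)
  structure(list(error_waveform = e, summary = mean(e), max_error = max(e)),
            class = "anomaly_score")
}

#' @export
print.anomaly_score <- function(x, ...) {
  cat(sprintf("<anomaly_score> mean %.4f, max %.4f\n", x$summary, x$max_error))
  invisible(x)
}
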