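# Run expr with a temporary RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Encoded flow field
#'
#' Component-normalized flow field: both components divided by the maximum
#' vector magnitude `n_max`, so all values lie in `[-1, 1]` (the currency of
#' FieldNet, whose layers are all tanh). `n_max = 0` is only valid for an
#' all-zero field.
#'
#' @param data `(h, w, 2)` array with values in `[-1, 1]`.
#' @param n_max normalization constant (pixels/frame), >= 0.
#' @return An object of class `encoded_field`.
#' @export
encoded_field <- function(data, n_max) {
  stopifnot(length(dim(data)) == 3L, dim(data)[3L] == 2L, n_max >= 0)
  if (max(abs(data)) > 1 + 1e-9)
    stop("encoded values must lie in [-1, 1]")
  if (n_max == 0 && any(data != 0))
    stop("n_max = 0 requires an all-zero encoding")
  structure(list(data = data, n_max = n_max), class = "encoded_field")
}

field_magnitudes <- function(field) sqrt(field[, , 1L]^2 + field[, , 2L]^2)

#' Encode a flow field for the network
#'
#' Parallel normalization of the x and y components by the maximum vector
#' magnitude, `[0, n_max] -> [-1, 1]` per component. With `n_max = "auto"`
#' the maximum magnitude of the field itself is used; pass the per-sequence
#' maximum instead to keep temporal magnitude comparability across a
#' sequence.
#'
#' @param field flow field `(h, w, 2)` array.
#' @param n_max positive magnitude, or `"auto"`.
#' @return An [encoded_field()].
#' @export
encode_field <- function(field, n_max = "auto") {
  stopifnot(all(is.finite(field)))
  if (identical(n_max, "auto")) n_max <- max(field_magnitudes(field))
  if (n_max == 0) {
    if (any(field != 0)) stop("n_max = 0 with a non-zero field")
    return(encoded_field(field * 0, 0))
  }
  if (n_max < 0) stop("n_max must be >= 0")
  data <- field / n_max
  data[data > 1] <- 1
  data[data < -1] <- -1
  encoded_field(data, n_max)
}

#' Decode an encoded field back to pixel units
#'
#' Inverse order of operations of [encode_field()]: multiply both components
#' by `n_max`.
#'
#' @param enc an [encoded_field()].
#' @return flow field `(h, w, 2)` array.
#' @export
decode_field <- function(enc) {
  stopifnot(inherits(enc, "encoded_field"))
  enc$data * enc$n_max
}

#' Angle/magnitude field encoding
#'
#' Encodes each vector's angle as the continuous pair
#' `(y1, y2) = (sin(theta), cos(theta))` scaled by `n/m` (magnitude over the
#' field maximum). Provided to verify the encoding equivalence: the angular
#' channels equal the direct component normalization with the two slices
#' interchanged, which is why the pipeline uses [encode_field()].
#'
#' @param field flow field `(h, w, 2)` array.
#' @return An [encoded_field()] with channels `(sin(theta), cos(theta)) * n/m`.
#' @export
encode_angular <- function(field) {
  stopifnot(all(is.finite(field)))
  n <- field_magnitudes(field)
  m <- max(n)
  if (m == 0) return(encoded_field(field * 0, 0))
  theta <- atan2(field[, , 2L], field[, , 1L])
  scale <- n / m
  y1 <- sin(theta) * scale
  y2 <- cos(theta) * scale
  y1[n == 0] <- 0
  y2[n == 0] <- 0
  out <- array(c(y1, y2), dim = dim(field))
  out[out > 1] <- 1; out[out < -1] <- -1
  encoded_field(out, m)
}

#' Zero the flow at face pixels
#'
#' @param field flow field `(h, w, 2)` array.
#' @param mask logical matrix of the same spatial shape; TRUE = face.
#' @return field with masked vectors set to `(0, 0)`.
#' @export
apply_face_mask <- function(field, mask) {
  d <- dim(field)
  if (!identical(dim(mask), d[1:2])) stop("mask shape must match field")
  field[, , 1L][mask] <- 0
  field[, , 2L][mask] <- 0
  field
}

#' Interleaved interpolation dataset
#'
#' Training currency of FieldNet: inputs stack the encoded fields at t and
#' t+2 into an `(h, w, 4)` tensor; the target is the intermediate field at
#' t+1, shape `(h, w, 2)`.
#'
#' @param x list of `(h, w, 4)` arrays.
#' @param y list of `(h, w, 2)` arrays.
#' @param split optional character vector of per-item tags (`"train"`/`"val"`).
#' @return An object of class `interleaved_dataset`.
#' @export
interleaved_dataset <- function(x, y, split = NULL) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  structure(list(x = x, y = y, split = split), class = "interleaved_dataset")
}

#' @export
length.interleaved_dataset <- function(x) length(x$x)

#' @export
print.interleaved_dataset <- function(x, ...) {
  d <- if (length(x) > 0) paste(dim(x$x[[1]])[1:2], collapse = "x") else "?"
  cat(sprintf("<interleaved_dataset> %d items, %s fields\n", length(x), d))
  invisible(x)
}

#' Collate encoded fields into the interleaved dataset
#'
#' Sliding stride-1 triples: item k pairs the stacked fields at k and k+2
#' with the intermediate field k+1 as target, yielding n-2 items from n
#' fields.
#'
#' @param fields list of [encoded_field()] (or raw `(h,w,2)` arrays), n >= 3.
#' @return An [interleaved_dataset()].
#' @export
collate_interleaved <- function(fields) {
  n <- length(fields)
  if (n < 3L) stop("need at least 3 fields")
  as_arr <- function(f) if (inherits(f, "encoded_field")) f$data else f
  fields <- lapply(fields, as_arr)
  d <- dim(fields[[1L]])
  x <- vector("list", n - 2L)
  y <- vector("list", n - 2L)
  for (k in seq_len(n - 2L)) {
    x[[k]] <- array(c(fields[[k]], fields[[k + 2L]]), dim = c(d[1:2], 4L))
    y[[k]] <- fields[[k + 1L]]
  }
  interleaved_dataset(x, y)
}

# Transform one (h,w,2) flow-like tensor: the grid layout and the vector
# components move together (hflip negates vx, vflip negates vy, rot90 maps
# (vx, vy) -> (-vy, vx), etc.).
transform_field2 <- function(a, op) {
  u <- a[, , 1L]; v <- a[, , 2L]
  switch(op,
    hflip = {
      u <- -u[, ncol(u):1, drop = FALSE]; v <- v[, ncol(v):1, drop = FALSE]
    },
    vflip = {
      u <- u[nrow(u):1, , drop = FALSE]; v <- -v[nrow(v):1, , drop = FALSE]
    },
    rot180 = {
      u <- -u[nrow(u):1, ncol(u):1, drop = FALSE]
      v <- -v[nrow(v):1, ncol(v):1, drop = FALSE]
    },
    rot90 = {
      if (nrow(u) != ncol(u)) stop("rot90/rot270 require square fields")
      gu <- t(u)[, nrow(u):1, drop = FALSE]
      gv <- t(v)[, nrow(v):1, drop = FALSE]
      u <- -gv; v <- gu
    },
    rot270 = {
      if (nrow(u) != ncol(u)) stop("rot90/rot270 require square fields")
      gu <- t(u)[ncol(u):1, , drop = FALSE]
      gv <- t(v)[ncol(v):1, , drop = FALSE]
      u <- gv; v <- -gu
    },
    stop("unknown augmentation op: ", op)
  )
  array(c(u, v), dim = c(nrow(u), ncol(u), 2L))
}

transform_tensor <- function(a, op) {
  nc <- dim(a)[3L]
  parts <- lapply(seq_len(nc / 2L), function(i)
    transform_field2(a[, , (2L * i - 1L):(2L * i), drop = FALSE], op))
  d <- dim(parts[[1L]])
  array(unlist(parts), dim = c(d[1:2], nc))
}

#' Augment an interleaved dataset
#'
#' Appends transformed copies of every item for each requested op. The
#' recording geometry places every subject on the left breathing rightward,
#' an instance bias that mirrored and rotated copies correct. Spatial
#' transforms act on both the grid layout and the vector components, so
#' per-field magnitude histograms are preserved exactly. Augmented copies
#' inherit the split tag of their source item.
#'
#' @param ds an [interleaved_dataset()].
#' @param ops subset of `c("hflip", "vflip", "rot90", "rot180", "rot270")`
#'   (rot90/rot270 require square fields).
#' @return the augmented [interleaved_dataset()].
#' @export
augment <- function(ds, ops = c("hflip", "vflip", "rot180")) {
  stopifnot(inherits(ds, "interleaved_dataset"))
  known <- c("hflip", "vflip", "rot90", "rot180", "rot270")
  bad <- setdiff(ops, known)
  if (length(bad)) stop("unknown augmentation op: ", paste(bad, collapse = ", "))
  x <- ds$x; y <- ds$y; split <- ds$split
  for (op in ops) {
    x <- c(x, lapply(ds$x, transform_tensor, op = op))
    y <- c(y, lapply(ds$y, transform_tensor, op = op))
    if (!is.null(split)) split <- c(split, ds$split)
  }
  interleaved_dataset(x, y, split)
}

#' Deterministic train/validation split
#'
#' Shuffled split at the stated fraction; the same seed always produces the
#' same partition, and no item lands in both sets.
#'
#' @param ds an [interleaved_dataset()].
#' @param train_fraction fraction of items in the training set (default 0.9).
#' @param seed integer RNG seed.
#' @return list with elements `train` and `val`, both [interleaved_dataset()].
#' @export
split_dataset <- function(ds, train_fraction = 0.9, seed = 1) {
  if (train_fraction <= 0 || train_fraction >= 1)
    stop("train_fraction must be in (0, 1)")
  n <- length(ds)
  idx <- with_seed(seed, sample.int(n))
  ntr <- round(train_fraction * n)
  tr <- sort(idx[seq_len(ntr)])
  va <- sort(idx[-seq_len(ntr)])
  list(train = interleaved_dataset(ds$x[tr], ds$y[tr]),
       val = interleaved_dataset(ds$x[va], ds$y[va]))
}
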