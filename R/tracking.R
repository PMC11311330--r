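#' Region of interest
#'
#' Fixed-size rectangular window, 1-based inclusive coordinates. The tracked
#' nose-mouth ROI keeps a constant size across a sequence (it matches the
#' input dimensionality of the flow model) and only its position changes.
#'
#' @param row0,col0 top-left corner (1-based, integer pixels).
#' @param height,width window size in pixels.
#' @return An object of class `roi`.
#' @export
roi <- function(row0, col0, height, width) {
  if (height < 1 || width < 1) stop("roi size must be positive")
  structure(list(row0 = as.integer(row0), col0 = as.integer(col0),
                 height = as.integer(height), width = as.integer(width)),
            class = "roi")
}

#' @export
print.roi <- function(x, ...) {
  cat(sprintf("<roi> top-left (%d, %d), %dx%d\n", x$row0, x$col0,
              x$height, x$width))
  invisible(x)
}

#' Crop a matrix to an ROI
#' @param frame a matrix.
#' @param r a [roi()] fully inside the frame.
#' @return the cropped sub-matrix.
#' @export
crop_roi <- function(frame, r) {
  if (r$row0 < 1 || r$col0 < 1 ||
      r$row0 + r$height - 1L > nrow(frame) ||
      r$col0 + r$width - 1L > ncol(frame))
    stop("roi must lie fully inside the frame")
  frame[r$row0:(r$row0 + r$height - 1L), r$col0:(r$col0 + r$width - 1L),
        drop = FALSE]
}

clamp_roi <- function(r, h, w) {
  row0 <- min(max(r$row0, 1L), h - r$height + 1L)
  col0 <- min(max(r$col0, 1L), w - r$width + 1L)
  clamped <- (row0 != r$row0) || (col0 != r$col0)
  list(roi = roi(row0, col0, r$height, r$width), clamped = clamped)
}

#' Detect corner key-points inside an ROI
#'
#' Shi-Tomasi style detector: minimum eigenvalue of the structure tensor
#' (Sobel gradients, Gaussian-smoothed tensor), thresholded at a fraction of
#' the maximum response, with 3x3 non-maximum suppression. Points are
#' returned in full-frame coordinates, strongest first.
#'
#' @param frame tracking-normalized frame (matrix in `[0,1]`).
#' @param r a [roi()].
#' @param max_points maximum number of points to return.
#' @param rel_threshold response threshold as a fraction of the maximum
#'   response (default 0.05).
#' @param margin border (pixels) inside the ROI excluded from detection so
#'   that the Lucas-Kanade window fits (default 8).
#' @param mask optional logical matrix (ROI-sized); detection is restricted
#'   to TRUE pixels (e.g. the face mask, so plume texture cannot capture
#'   key-points).
#' @return integer matrix with columns `row`, `col` (possibly 0 rows).
#' @export
detect_keypoints <- function(frame, r, max_points = 25, rel_threshold = 0.05,
                             margin = 8, mask = NULL) {
  if (max_points < 1) stop("max_points must be >= 1")
  crop <- crop_roi(frame, r)
  ix <- conv3x3_reflect(crop, sobel_x_kernel())
  iy <- conv3x3_reflect(crop, sobel_y_kernel())
  axx <- gauss_blur(ix * ix, 1)
  axy <- gauss_blur(ix * iy, 1)
  ayy <- gauss_blur(iy * iy, 1)
  tr <- axx + ayy
  dd <- sqrt(pmax((axx - ayy)^2 + 4 * axy^2, 0))
  resp <- (tr - dd) / 2  # minimum eigenvalue
  h <- nrow(resp); w <- ncol(resp)
  m <- min(margin, floor((min(h, w) - 1) / 2))
  keep <- matrix(FALSE, h, w)
  if (h > 2 * m && w > 2 * m)
    keep[(m + 1L):(h - m), (m + 1L):(w - m)] <- TRUE
  if (!is.null(mask)) keep <- keep & mask
  resp[!keep] <- -Inf
  mx <- max(resp)
  if (!is.finite(mx) || mx <= 1e-12)
    return(matrix(integer(0), 0, 2, dimnames = list(NULL, c("row", "col"))))
  thr <- rel_threshold * mx
  # 3x3 non-maximum suppression
  p <- matrix(-Inf, h + 2L, w + 2L)
  p[2:(h + 1L), 2:(w + 1L)] <- resp
  ismax <- resp >= thr
  for (dr in -1:1) for (dc in -1:1) {
    if (dr == 0 && dc == 0) next
    ismax <- ismax & (resp >= p[(2L + dr):(h + 1L + dr), (2L + dc):(w + 1L + dc)])
  }
  idx <- which(ismax, arr.ind = TRUE)
  if (nrow(idx) == 0L)
    return(matrix(integer(0), 0, 2, dimnames = list(NULL, c("row", "col"))))
  ord <- order(resp[ismax], decreasing = TRUE)
  idx <- idx[ord, , drop = FALSE][seq_len(min(max_points, nrow(idx))), , drop = FALSE]
  out <- cbind(row = idx[, 1L] + r$row0 - 1L, col = idx[, 2L] + r$col0 - 1L)
  out
}

# Iterative single-level Lucas-Kanade displacement of one key-point. The
# template window sits at (anchor_row, anchor_col) in `prev`; the search in
# `cur` is warm-started at (row, col). Returns the total displacement
# c(drow, dcol) relative to the anchor, or NULL when the window is
# degenerate or the point is lost.
lk_point <- function(prev, cur, row, col, half, n_iter,
                     anchor_row = row, anchor_col = col) {
  h <- nrow(prev); w <- ncol(prev)
  if (anchor_row - half < 2 || anchor_col - half < 2 ||
      anchor_row + half > h - 1 || anchor_col + half > w - 1)
    return(NULL)
  rs <- (anchor_row - half):(anchor_row + half)
  cs <- (anchor_col - half):(anchor_col + half)
  tmpl <- prev[rs, cs]
  # template gradients (central differences)
  gx <- (prev[rs, cs + 1L] - prev[rs, cs - 1L]) / 2
  gy <- (prev[rs + 1L, cs] - prev[rs - 1L, cs]) / 2
  gxx <- sum(gx * gx); gxy <- sum(gx * gy); gyy <- sum(gy * gy)
  det <- gxx * gyy - gxy * gxy
  if (det < 1e-12) return(NULL)
  # reject weak-texture windows (smallest eigenvalue of the normal matrix)
  lam_min <- ((gxx + gyy) - sqrt((gxx - gyy)^2 + 4 * gxy^2)) / 2
  if (lam_min / length(tmpl) < 1e-7) return(NULL)
  rr <- matrix(rs, length(rs), length(cs))
  cc <- matrix(cs, length(rs), length(cs), byrow = TRUE)
  d0 <- c(row - anchor_row, col - anchor_col)
  d <- d0
  for (i in seq_len(n_iter)) {
    samp <- matrix(bilinear_sample(cur, rr + d[1L], cc + d[2L]), length(rs))
    err <- samp - tmpl
    bx <- sum(gx * err); by <- sum(gy * err)
    step <- c(gyy * by - gxy * bx, gxx * bx - gxy * by) / det
    # a single Gauss-Newton step larger than 1 px is outside the
    # linearization's trust region
    sl <- sqrt(sum(step^2))
    if (sl > 1) step <- step / sl
    d <- d - step
    if (sum((d - d0)^2) > half^2) return(NULL)    # point lost
    if (sl < 1e-4) break
  }
  d
}

dead_band_round <- function(x) {
  ifelse(abs(x) < 0.5, 0L, as.integer(sign(x) * floor(abs(x) + 0.5)))
}

#' Estimate the inter-frame ROI shift from key-points
#'
#' Runs single-level iterative Lucas-Kanade flow at each key-point, takes the
#' per-component median displacement, and quantizes it with a +-0.5 px
#' dead-band so that sub-pixel jitter does not move the ROI.
#'
#' @param prev,cur tracking-normalized frames.
#' @param keypoints integer matrix with columns `row`, `col`.
#' @param window odd LK window size in pixels (default 15).
#' @param n_iter LK iterations (default 10).
#' @param presmooth Gaussian sigma applied to both frames before the
#'   gradient computation (default 1; 0 disables). Damps sensor noise.
#' @return list with `shift` (integer `c(drow, dcol)`), `raw` (the median
#'   sub-pixel displacement) and `low_confidence` (TRUE when no key-point
#'   produced a usable estimate).
#' @export
estimate_shift <- function(prev, cur, keypoints, window = 15, n_iter = 10,
                           presmooth = 1) {
  if (presmooth > 0) {
    prev <- gauss_blur(prev, presmooth)
    cur <- gauss_blur(cur, presmooth)
  }
  half <- (window - 1L) %/% 2L
  ds <- NULL
  if (!is.null(keypoints) && nrow(keypoints) > 0L) {
    for (k in seq_len(nrow(keypoints))) {
      d <- lk_point(prev, cur, keypoints[k, 1L], keypoints[k, 2L], half, n_iter)
      if (!is.null(d)) ds <- rbind(ds, d)
    }
  }
  if (is.null(ds) || nrow(ds) == 0L)
    return(list(shift = c(0L, 0L), raw = c(0, 0), low_confidence = TRUE))
  raw <- c(stats::median(ds[, 1L]), stats::median(ds[, 2L]))
  list(shift = dead_band_round(raw), raw = raw, low_confidence = FALSE)
}

#' Track the nose-mouth ROI through a sequence
#'
#' Anchor-based tracking: key-points are detected inside the ROI on an
#' anchor frame, and each subsequent frame's cumulative displacement
#' relative to that anchor is estimated by median-aggregated Lucas-Kanade
#' flow (warm-started from the previous frame's displacement). Estimating
#' against a fixed anchor rather than frame-to-frame keeps per-frame noise
#' from integrating into spurious drift; a 0.6 px hysteresis on the integer
#' ROI position minimizes the per-frame jump. The anchor is refreshed every
#' `refresh_every` frames, when fewer than 3 key-points survive, or when
#' the accumulated displacement approaches the Lucas-Kanade window radius.
#'
#' @param seq a [thermal_sequence].
#' @param initial_roi the fixed-size [roi()] in frame 1.
#' @param params a [norm_params()] used for tracking normalization.
#' @param max_points,window,n_iter,refresh_every tracker settings.
#' @return list of [roi()] (one per frame) with attributes `shift_history`
#'   ((n-1) x 2 integer matrix of applied shifts) and `flags` (per-frame:
#'   `"ok"`, `"low_confidence"` or `"clamped"`).
#' @export
track_sequence <- function(seq, initial_roi, params, max_points = 25,
                           window = 15, n_iter = 10, refresh_every = 25,
                           face_threshold = 0.85) {
  stopifnot(inherits(seq, "thermal_sequence"))
  kp_detect <- function(frame, r) {
    msk <- frame >= face_threshold
    msk <- crop_roi(msk, r)
    if (!any(msk)) msk <- NULL    # featureless fallback: unrestricted
    detect_keypoints(frame, r, max_points, mask = msk)
  }
  n <- length(seq$frames)
  rois <- vector("list", n)
  cl <- clamp_roi(initial_roi, seq$height, seq$width)
  rois[[1L]] <- cl$roi
  flags <- character(n)
  flags[1L] <- if (cl$clamped) "clamped" else "ok"
  shift_history <- matrix(0L, max(n - 1L, 0L), 2L,
                          dimnames = list(NULL, c("drow", "dcol")))
  half <- (window - 1L) %/% 2L
  anchor <- gauss_blur(normalize_frame(seq$frames[[1L]], params, "tracking"), 1)
  kp <- kp_detect(anchor, rois[[1L]])
  disp <- c(0, 0)        # cumulative sub-pixel displacement since anchor
  offset <- c(0L, 0L)    # integer ROI offset since anchor
  since_refresh <- 0L
  for (t in seq_len(n - 1L)) {
    cur <- gauss_blur(normalize_frame(seq$frames[[t + 1L]], params,
                                      "tracking"), 1)
    since_refresh <- since_refresh + 1L
    refresh <- nrow(kp) == 0L || since_refresh >= refresh_every ||
      max(abs(disp)) > half - 3
    if (refresh) {
      anchor <- gauss_blur(normalize_frame(seq$frames[[t]], params,
                                           "tracking"), 1)
      kp2 <- kp_detect(anchor, rois[[t]])
      if (nrow(kp2) > 0L || nrow(kp) == 0L) kp <- kp2
      disp <- c(0, 0)
      offset <- c(0L, 0L)
      since_refresh <- 0L
    }
    # warm start: sample around the integer part of the last displacement
    guess <- round(disp)
    ds <- NULL
    if (nrow(kp) > 0L) {
      for (k in seq_len(nrow(kp))) {
        d <- lk_point(anchor, cur, kp[k, 1L] + guess[1L], kp[k, 2L] + guess[2L],
                      half, n_iter, anchor_row = kp[k, 1L],
                      anchor_col = kp[k, 2L])
        if (!is.null(d)) ds <- rbind(ds, d)
      }
    }
    low_conf <- is.null(ds)
    if (!low_conf)
      disp <- c(stats::median(ds[, 1L]), stats::median(ds[, 2L]))
    # hysteresis: only move the integer ROI when the estimate departs from
    # the current offset by more than 0.6 px
    step <- disp - offset
    move <- ifelse(abs(step) >= 0.6, round(step), 0)
    offset <- as.integer(offset + move)
    cand <- roi(rois[[t]]$row0 + move[1L], rois[[t]]$col0 + move[2L],
                rois[[t]]$height, rois[[t]]$width)
    cl <- clamp_roi(cand, seq$height, seq$width)
    rois[[t + 1L]] <- cl$roi
    applied <- c(rois[[t + 1L]]$row0 - rois[[t]]$row0,
                 rois[[t + 1L]]$col0 - rois[[t]]$col0)
    shift_history[t, ] <- as.integer(applied)
    flags[t + 1L] <- if (cl$clamped) "clamped"
                     else if (low_conf) "low_confidence" else "ok"
  }
  structure(rois, shift_history = shift_history, flags = flags)
}

#' Remove ROI-induced uniform motion from a flow field
#'
#' A moving ROI superimposes a uniform translation on every flow vector
#' computed inside it; the inverse transformation subtracts that uniform
#' motion so a static background yields near-zero vectors. `shift` is the
#' uniform motion present in the field, as `c(drow, dcol)`: for an ROI that
#' moved by `(dr, dc)` between the two frames, the induced background motion
#' in crop coordinates is `(-dr, -dc)`.
#'
#' @param field a flow field, `(h, w, 2)` array (channel 1 = vx along
#'   columns, channel 2 = vy along rows).
#' @param shift numeric `c(drow, dcol)` uniform motion to remove.
#' @return the compensated flow field.
#' @export
compensate_shift <- function(field, shift) {
  stopifnot(length(dim(field)) == 3L, dim(field)[3L] == 2L)
  field[, , 1L] <- field[, , 1L] - shift[2L]
  field[, , 2L] <- field[, , 2L] - shift[1L]
  field
}

#' Face mask for flow zeroing
#'
#' Pixels whose tracking-normalized value exceeds the face threshold are
#' labelled face and dilated, so that facial motion (including sub-pixel
#' drift of the warm face edge, which otherwise produces flow humps on the
#' scale of real exhales) does not contribute to the exhale flow signal.
#' The tracking map clamps the ambient background to exactly 0, so on an
#' exhale-free frame any stable value above the noise floor marks the face
#' footprint; the default threshold 0.15 captures the full footprint while
#' plume-free background stays excluded. A higher threshold (e.g. 0.85)
#' restricts the mask to the face core.
#'
#' @param norm_roi tracking-normalized ROI crop (matrix in `[0,1]`),
#'   ideally from a frame without an active exhale.
#' @param threshold face threshold (default 0.05).
#' @param dilate dilation radius in pixels (default 4).
#' @return logical matrix, TRUE = face.
#' @export
make_face_mask <- function(norm_roi, threshold = 0.05, dilate = 4) {
  dilate_mask(norm_roi >= threshold, dilate)
}
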