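#' Dense flow parameters
#'
#' `alpha` weighs the smoothness term against the brightness-constancy term.
#' Small values (default 0.15) keep intensity shifts close to the sensor
#' noise floor as valid flow contributions, which is what makes dissipating
#' exhale plumes measurable. Note the update denominator is
#' `alpha + Ix^2 + Iy^2` (not `alpha^2` as in the classical formulation);
#' since `alpha` is free either behaviour is reachable.
#'
#' @param alpha smoothness weight, > 0 (default 0.15).
#' @param n_iter number of iterations of the coupled update (default 64).
#' @return An object of class `flow_params`.
#' @export
flow_params <- function(alpha = 0.15, n_iter = 64) {
  if (alpha <= 0) stop("alpha must be > 0")
  if (n_iter < 1) stop("n_iter must be >= 1")
  structure(list(alpha = alpha, n_iter = as.integer(n_iter)),
            class = "flow_params")
}

#' Construct a flow field array
#'
#' @param u matrix of x-components (vx, along columns, pixels/frame).
#' @param v matrix of y-components (vy, along rows, pixels/frame).
#' @return `(h, w, 2)` array; channel 1 = vx, channel 2 = vy.
#' @export
flow_field <- function(u, v) {
  stopifnot(identical(dim(u), dim(v)))
  if (!all(is.finite(u)) || !all(is.finite(v)))
    stop("flow field must be finite everywhere")
  array(c(u, v), dim = c(nrow(u), ncol(u), 2L))
}

#' Sobel spatial gradients
#'
#' 3x3 Sobel convolution normalized by 1/8 (a unit intensity ramp has unit
#' gradient), reflective border handling.
#'
#' @param frame numeric matrix, at least 3x3.
#' @return list with matrices `Ix` (d/dx, columns) and `Iy` (d/dy, rows).
#' @export
spatial_gradients <- function(frame) {
  if (nrow(frame) < 3 || ncol(frame) < 3)
    stop("frame must be at least 3x3")
  list(Ix = conv3x3_reflect(frame, sobel_x_kernel()),
       Iy = conv3x3_reflect(frame, sobel_y_kernel()))
}

# Horn-Schunck neighbourhood average: 3x3 weighted stencil with 1/6 on the
# 4-neighbours and 1/12 on the diagonals, reflective borders.
hs_average <- function(m) {
  k <- matrix(c(1/12, 1/6, 1/12, 1/6, 0, 1/6, 1/12, 1/6, 1/12), 3, 3)
  conv3x3_reflect(m, k)
}

#' Dense Horn-Schunck optical flow
#'
#' Iterative minimization of the brightness-constancy and smoothness energy
#' between two normalized frames. Spatial derivatives are Sobel gradients of
#' the first frame; the temporal derivative is the pointwise frame
#' difference. Starting from zero flow, each iteration replaces the field by
#' its neighbourhood average corrected along the image gradient:
#' `v <- vbar - g * (Ix*vbar_x + Iy*vbar_y + It) / (alpha + Ix^2 + Iy^2)`.
#' The result is deterministic for fixed inputs and parameters; two
#' identical frames give an exactly zero field for any iteration count.
#'
#' @param f1,f2 normalized frames of identical dimension.
#' @param params a [flow_params()].
#' @return flow field `(h, w, 2)` array (see [flow_field()]).
#' @export
horn_schunck <- function(f1, f2, params = flow_params()) {
  if (!identical(dim(f1), dim(f2))) stop("frames must have identical shape")
  if (!all(is.finite(f1)) || !all(is.finite(f2)))
    stop("frames must be finite")
  g <- spatial_gradients(f1)
  ix <- g$Ix; iy <- g$Iy
  it <- f2 - f1
  denom <- params$alpha + ix^2 + iy^2
  u <- matrix(0, nrow(f1), ncol(f1))
  v <- matrix(0, nrow(f1), ncol(f1))
  for (i in seq_len(params$n_iter)) {
    ub <- hs_average(u)
    vb <- hs_average(v)
    common <- (ix * ub + iy * vb + it) / denom
    u <- ub - ix * common
    v <- vb - iy * common
  }
  flow_field(u, v)
}

#' Flow fields for a tracked sequence
#'
#' Computes the dense flow between ROI crops of consecutive exhale-normalized
#' frames. For each frame pair both crops are taken at the *later* frame's
#' tracked ROI: holding the window fixed per pair applies the exact inverse
#' of the ROI transformation, so the integer ROI shift induces no uniform
#' motion and a static background yields near-zero vectors by construction.
#' (Subtracting the induced motion from the solved field instead, via
#' [compensate_shift()], is only exact where the image has enough gradient
#' for the solver to observe the shift; over a textureless background it
#' injects the full shift as spurious flow.) Optionally zeroes face pixels.
#'
#' @param frames list of exhale-normalized full frames (length n >= 2).
#' @param rois list of [roi()] aligned with `frames` (constant size).
#' @param params a [flow_params()].
#' @param mask optional logical face mask (ROI-sized). Masked pixels are
#'   blanked in the input crops *before* the solve -- otherwise the moving
#'   face texture would bleed flow into unmasked pixels through the
#'   smoothness term -- and the corresponding vectors are zeroed in the
#'   output, leaving the zero regions the encoder expects.
#' @return list of n-1 flow fields.
#' @export
flow_sequence <- function(frames, rois, params = flow_params(), mask = NULL) {
  n <- length(frames)
  if (n < 2L) stop("need at least 2 frames")
  if (length(rois) != n) stop("rois must align with frames")
  fields <- vector("list", n - 1L)
  for (t in seq_len(n - 1L)) {
    c1 <- crop_roi(frames[[t]], rois[[t + 1L]])
    c2 <- crop_roi(frames[[t + 1L]], rois[[t + 1L]])
    if (!is.null(mask)) {
      c1[mask] <- 0
      c2[mask] <- 0
    }
    fld <- horn_schunck(c1, c2, params)
    if (!is.null(mask))
      fld <- apply_face_mask(fld, mask)
    fields[[t]] <- fld
  }
  fields
}
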