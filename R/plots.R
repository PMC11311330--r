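#' Plot an exhale waveform
#'
#' @param x an [exhale_waveform()].
#' @param ... passed to [graphics::plot()].
#' @export
plot.exhale_waveform <- function(x, ...) {
  tt <- (seq_along(x$samples) - 1) / x$fps
  graphics::plot(tt, x$samples, type = "l", xlab = "time [s]",
                 ylab = "flow sum f(t)", main = x$provenance, ...)
  invisible(x)
}

#' Plot a flow field as arrows
#'
#' Line-segment rendering of the vector field at a pixel stride, scaled for
#' visibility; colour encodes magnitude.
#'
#' @param field `(h, w, 2)` flow field.
#' @param stride arrow stride in pixels (default 2).
#' @param scale arrow length multiplier (default 2).
#' @export
plot_flow_field <- function(field, stride = 2, scale = 2) {
  d <- dim(field)
  rs <- seq(1L, d[1L], by = stride)
  cs <- seq(1L, d[2L], by = stride)
  u <- field[rs, cs, 1L]; v <- field[rs, cs, 2L]
  mag <- sqrt(u^2 + v^2)
  cols <- grDevices::hcl.colors(16, "viridis")[
    pmin(15L, floor(15 * mag / max(mag, 1e-12))) + 1L]
  cc <- rep(cs, each = length(rs))
  rr <- rep(rs, times = length(cs))
  graphics::plot(NA, xlim = c(1, d[2L]), ylim = c(d[1L], 1), asp = 1,
                 xlab = "col", ylab = "row", main = "flow field")
  keep <- mag > 0
  graphics::segments(cc[keep], rr[keep],
                     cc[keep] + scale * u[keep], rr[keep] + scale * v[keep],
                     col = cols[keep])
  invisible(field)
}

#' Plot a segment with its anomaly scale
#'
#' The input exhale segment coloured by the predicted per-sample anomaly
#' error.
#'
#' @param x an `anomaly_score`.
#' @param segment the scored [exhale_segment()].
#' @param ... unused.
#' @export
plot.anomaly_score <- function(x, segment, ...) {
  v <- if (inherits(segment, "exhale_segment")) segment$values else segment
  e <- x$error_waveform
  cols <- grDevices::hcl.colors(16, "Inferno")[
    pmin(15L, floor(15 * e / max(e, 1e-12))) + 1L]
  graphics::plot(seq_along(v), v, type = "n", xlab = "sample",
                 ylab = "f(t)", main = sprintf("anomaly %.3f", x$summary))
  graphics::segments(seq_along(v)[-1] - 1L, v[-length(v)],
                     seq_along(v)[-1], v[-1], col = cols[-1], lwd = 2)
  invisible(x)
}
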