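#' Reduce a flow field to a scalar flow sample
#'
#' The sum of all vector magnitudes over the ROI: nonnegative, zero only for
#' an all-zero field, and invariant under right-angle rotations and
#' reflections of the field. One flow field contributes one waveform sample.
#'
#' @param field flow field `(h, w, 2)` array.
#' @return scalar `sum(sqrt(vx^2 + vy^2))`.
#' @export
reduce_field <- function(field) {
  stopifnot(all(is.finite(field)))
  sum(field_magnitudes(field))
}

#' Exhale waveform
#'
#' One-dimensional time series of per-field flow sums: the measurement
#' currency of the pipeline. Raw samples are in arbitrary flow units
#' (pixels/frame summed over the ROI); after [filter_waveform()] they live
#' in `[0, 1]`.
#'
#' @param samples numeric vector of flow sums.
#' @param fps samples per second.
#' @param provenance `"raw_optical_flow"` or `"fieldnet_predicted"`.
#' @param processing character vector of applied filter names.
#' @return An object of class `exhale_waveform`.
#' @export
exhale_waveform <- function(samples, fps = 25,
                            provenance = c("raw_optical_flow",
                                           "fieldnet_predicted"),
                            processing = character()) {
  provenance <- match.arg(provenance)
  if (!all(is.finite(samples))) stop("samples must be finite")
  structure(list(samples = as.numeric(samples), fps = fps,
                 provenance = provenance, processing = processing),
            class = "exhale_waveform")
}

#' @export
print.exhale_waveform <- function(x, ...) {
  cat(sprintf("<exhale_waveform> %d samples @ %g fps (%s)\n",
              length(x$samples), x$fps, x$provenance))
  if (length(x$processing))
    cat("  processing:", paste(x$processing, collapse = " -> "), "\n")
  invisible(x)
}

#' @export
length.exhale_waveform <- function(x) length(x$samples)

#' Build the exhale waveform from a field sequence
#'
#' @param fields non-empty list of flow fields.
#' @param fps frame rate of the source sequence.
#' @param provenance see [exhale_waveform()].
#' @return An [exhale_waveform()] with one sample per field, order preserved.
#' @export
build_waveform <- function(fields, fps = 25, provenance = "raw_optical_flow") {
  if (length(fields) == 0L) stop("need at least one field")
  exhale_waveform(vapply(fields, reduce_field, numeric(1)), fps = fps,
                  provenance = provenance)
}

#' Filter an exhale waveform
#'
#' Three steps, in order: (1) outlier removal — samples farther than
#' `sd_limit` standard deviations from the mean are replaced by linear
#' interpolation of their neighbours (replacement rather than deletion keeps
#' the sample count aligned with the frame clock); (2) Savitzky-Golay
#' smoothing, window 9, polynomial order 3; (3) min-max normalization to
#' `[0, 1]`. A constant signal cannot be min-max normalized: the result is
#' all zeros with attribute `degenerate = TRUE`.
#'
#' @param w an [exhale_waveform()] with at least 9 samples.
#' @param sd_limit outlier threshold in standard deviations (default 1.5).
#' @param sg_window,sg_order Savitzky-Golay window and polynomial order.
#' @return the filtered [exhale_waveform()] (attribute `degenerate` when the
#'   input was constant).
#' @export
filter_waveform <- function(w, sd_limit = 1.5, sg_window = 9, sg_order = 3) {
  stopifnot(inherits(w, "exhale_waveform"))
  x <- w$samples
  if (length(x) < sg_window) stop("need at least ", sg_window, " samples")
  mu <- mean(x); s <- stats::sd(x)
  out <- if (s > 0) abs(x - mu) > sd_limit * s else rep(FALSE, length(x))
  if (any(out) && !all(out)) {
    idx <- seq_along(x)
    x[out] <- stats::approx(idx[!out], x[!out], xout = idx[out],
                            rule = 2)$y
  }
  x <- as.numeric(signal::sgolayfilt(x, p = sg_order, n = sg_window))
  rng <- range(x)
  # constant up to Savitzky-Golay round-off
  degenerate <- (rng[2L] - rng[1L]) <= 1e-9 * max(1, abs(rng[1L]), abs(rng[2L]))
  x <- if (degenerate) rep(0, length(x)) else (x - rng[1L]) / (rng[2L] - rng[1L])
  out_w <- exhale_waveform(x, fps = w$fps, provenance = w$provenance,
                           processing = c(w$processing, "outlier_removal",
                                          "savitzky_golay", "minmax"))
  attr(out_w, "degenerate") <- degenerate
  out_w
}

# Local maxima with prominence and minimum separation. Prominence of a peak:
# height above the higher of the two deepest valleys separating it from
# higher terrain (standard topographic definition on the 1-D signal).
find_peaks <- function(x, min_prominence = 0, min_separation = 1) {
  n <- length(x)
  if (n < 3L) return(integer())
  cand <- which(diff(sign(diff(x))) < 0) + 1L
  if (length(cand) == 0L) return(integer())
  prom <- vapply(cand, function(p) {
    left <- x[seq_len(p - 1L)]
    higher_l <- which(left > x[p])
    lbase <- if (!length(higher_l)) min(left)
             else if (max(higher_l) == p - 1L) x[p]
             else min(x[(max(higher_l) + 1L):(p - 1L)])
    right <- x[(p + 1L):n]
    higher_r <- which(right > x[p])
    rbase <- if (!length(higher_r)) min(right)
             else if (min(higher_r) == 1L) x[p]
             else min(right[seq_len(min(higher_r) - 1L)])
    x[p] - max(lbase, rbase)
  }, numeric(1))
  keep <- cand[prom >= min_prominence]
  promk <- prom[prom >= min_prominence]
  # enforce separation, strongest first
  ord <- order(promk, decreasing = TRUE)
  sel <- integer()
  for (i in ord) {
    if (all(abs(keep[i] - sel) >= min_separation)) sel <- c(sel, keep[i])
  }
  sort(sel)
}

#' Exhale segment
#'
#' One exhale episode, resampled to the fixed network input length of 256
#' samples in `[0, 1]`.
#'
#' @param values numeric vector of length 256.
#' @param source_bounds integer `c(start, end)` indices in the parent
#'   waveform.
#' @return An object of class `exhale_segment`.
#' @export
exhale_segment <- function(values, source_bounds = c(NA_integer_, NA_integer_)) {
  if (length(values) != 256L) stop("segment length must be exactly 256")
  structure(list(values = as.numeric(values),
                 source_bounds = as.integer(source_bounds)),
            class = "exhale_segment")
}

#' @export
print.exhale_segment <- function(x, ...) {
  cat(sprintf("<exhale_segment> 256 samples, source [%d, %d], peak %.3f\n",
              x$source_bounds[1L], x$source_bounds[2L], max(x$values)))
  invisible(x)
}

resample_segment <- function(values, n = 256L) {
  if (length(values) == 1L) return(rep(values, n))
  stats::approx(seq_along(values), values,
                xout = seq(1, length(values), length.out = n))$y
}

#' Segment a filtered waveform into individual exhales
#'
#' Exhale peaks are detected subject to prominence and separation
#' thresholds; the waveform minima between consecutive peaks (and the
#' waveform ends) delimit the episodes, and each inter-minima span is
#' linearly resampled to length 256. Boundaries are strictly increasing and
#' segments do not overlap.
#'
#' @param w a filtered [exhale_waveform()] with samples in `[0, 1]`.
#' @param min_separation minimum peak separation in seconds (default 0.5).
#' @param min_prominence minimum peak prominence as a fraction of the
#'   normalized range (default 0.1).
#' @return list of [exhale_segment()]s (empty when no peak qualifies).
#' @export
segment_exhales <- function(w, min_separation = 0.5, min_prominence = 0.1) {
  stopifnot(inherits(w, "exhale_waveform"))
  x <- w$samples
  if (min(x) < -1e-9 || max(x) > 1 + 1e-9)
    stop("segment_exhales expects a filtered waveform in [0, 1]")
  sep <- max(1L, round(min_separation * w$fps))
  peaks <- find_peaks(x, min_prominence = min_prominence, min_separation = sep)
  if (length(peaks) == 0L) return(list())
  bounds <- integer(length(peaks) + 1L)
  bounds[1L] <- 1L
  if (length(peaks) > 1L) {
    for (i in seq_len(length(peaks) - 1L)) {
      span <- peaks[i]:peaks[i + 1L]
      bounds[i + 1L] <- span[which.min(x[span])]
    }
  }
  bounds[length(bounds)] <- length(x)
  segs <- vector("list", length(peaks))
  for (i in seq_along(peaks)) {
    a <- bounds[i]; b <- bounds[i + 1L]
    segs[[i]] <- exhale_segment(resample_segment(x[a:b]), c(a, b))
  }
  segs
}

#' Breathing rate of a segmented waveform
#'
#' @param w the filtered [exhale_waveform()].
#' @param segments output of [segment_exhales()].
#' @return breaths per minute implied by the segment count over the
#'   recording duration.
#' @export
breathing_rate <- function(w, segments) {
  dur_min <- length(w$samples) / w$fps / 60
  length(segments) / dur_min
}
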