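#' Thermal image sequence
#'
#' Ordered frames of raw 16-bit sensor counts as produced by a mid-wave
#' infrared camera. Each frame is an integer matrix of *counts* (sensor
#' activations prior to radiometric calibration); indoor scenes typically sit
#' in the 5000--9000 count range.
#'
#' @param frames list of integer matrices, all of identical dimension, with
#'   values in `[0, 65535]`.
#' @param fps frame rate in frames per second (default 25).
#' @return An object of class `thermal_sequence` with elements `frames`,
#'   `fps`, `height`, `width`.
#' @export
thermal_sequence <- function(frames, fps = 25) {
  if (!is.list(frames) || length(frames) == 0L)
    stop("`frames` must be a non-empty list of matrices")
  d <- dim(frames[[1L]])
  for (f in frames) {
    if (!is.matrix(f) || !identical(dim(f), d))
      stop("all frames must be matrices sharing one dimension")
    if (anyNA(f) || min(f) < 0 || max(f) > 65535)
      stop("counts must lie in [0, 65535]")
  }
  structure(list(frames = frames, fps = fps, height = d[1L], width = d[2L]),
            class = "thermal_sequence")
}

#' @export
print.thermal_sequence <- function(x, ...) {
  cat(sprintf("<thermal_sequence> %d frames of %dx%d @ %g fps\n",
              length(x$frames), x$height, x$width, x$fps))
  rng <- range(vapply(x$frames, range, numeric(2)))
  cat(sprintf("  count range: [%d, %d]\n", rng[1L], rng[2L]))
  invisible(x)
}

#' @export
length.thermal_sequence <- function(x) length(x$frames)

#' Read a raw 16-bit binary thermal sequence
#'
#' Sequences are stored as headerless contiguous binary files: frame-major,
#' row-major within each frame, unsigned 16-bit counts. Frame geometry is not
#' part of the format and must be supplied.
#'
#' @param path file path.
#' @param height,width frame dimensions in pixels.
#' @param endian byte order of the 16-bit counts, `"little"` (default,
#'   dominant sensor convention) or `"big"`.
#' @param fps frame rate recorded alongside the frames (default 25).
#' @return A [thermal_sequence].
#' @export
read_sequence <- function(path, height, width, endian = "little", fps = 25) {
  if (height <= 0 || width <= 0) stop("height and width must be positive")
  sz <- file.size(path)
  if (is.na(sz)) stop("cannot stat file: ", path)
  stride <- height * width * 2
  if (sz == 0 || sz %% stride != 0)
    stop(sprintf("malformed file: size %d is not a positive multiple of frame stride %d",
                 sz, stride))
  n <- sz %/% stride
  con <- file(path, "rb")
  on.exit(close(con))
  raw <- readBin(con, "integer", n = n * height * width, size = 2,
                 signed = FALSE, endian = endian)
  frames <- vector("list", n)
  for (k in seq_len(n)) {
    off <- (k - 1L) * height * width
    # row-major on disk; R matrices are column-major
    frames[[k]] <- matrix(raw[(off + 1L):(off + height * width)],
                          nrow = height, ncol = width, byrow = TRUE)
  }
  thermal_sequence(frames, fps = fps)
}

#' Write a thermal sequence to the raw binary format
#'
#' Inverse of [read_sequence()]; the round trip is bit-exact.
#'
#' @param seq a [thermal_sequence].
#' @param path output file path.
#' @param endian byte order, as in [read_sequence()].
#' @return `path`, invisibly.
#' @export
write_sequence <- function(seq, path, endian = "little") {
  stopifnot(inherits(seq, "thermal_sequence"))
  con <- file(path, "wb")
  on.exit(close(con))
  for (f in seq$frames) {
    v <- as.integer(t(f))  # row-major
    # writeBin has no unsigned 16-bit mode: map [32768,65535] onto the
    # negative two's-complement range
    v[v > 32767L] <- v[v > 32767L] - 65536L
    writeBin(v, con, size = 2, endian = endian)
  }
  invisible(path)
}

#' Normalization parameters for count images
#'
#' `Fc` is the count corresponding to face temperature, `Ac` the general
#' ambient (background) count sampled from a background region, and `Imax`
#' the top count anchor used by the tracking normalization. Exhale
#' intensities fall between `Ac` and `Fc`.
#'
#' @param Fc face-temperature count.
#' @param Ac ambient background count; must satisfy `Ac < Fc`.
#' @param Imax maximum count for tracking normalization; `Fc <= Imax`.
#' @return An object of class `norm_params`.
#' @export
norm_params <- function(Fc, Ac, Imax = 65535) {
  if (!(Ac < Fc && Fc <= Imax))
    stop("norm_params require Ac < Fc <= Imax")
  structure(list(Fc = Fc, Ac = Ac, Imax = Imax), class = "norm_params")
}

#' Estimate the ambient background count
#'
#' Samples counts inside a background region and returns their median, a
#' location estimate robust to hot pixels.
#'
#' @param frame integer matrix of counts.
#' @param region a [roi()] lying inside the frame.
#' @return scalar ambient count estimate.
#' @export
estimate_ambient <- function(frame, region) {
  px <- crop_roi(frame, region)
  if (length(px) == 0L) stop("empty background region")
  stats::median(as.numeric(px))
}

#' Estimate the face-temperature count
#'
#' Default helper: the 99th percentile of counts inside the tracked face
#' region, which sits at the top of the face-pixel distribution while
#' ignoring isolated hot pixels.
#'
#' @param frame integer matrix of counts.
#' @param face_region a [roi()] covering the face.
#' @param prob quantile used (default 0.99).
#' @return scalar face count estimate.
#' @export
estimate_face_count <- function(frame, face_region, prob = 0.99) {
  px <- crop_roi(frame, face_region)
  if (length(px) == 0L) stop("empty face region")
  as.numeric(stats::quantile(as.numeric(px), prob, names = FALSE))
}

#' Estimate both normalization parameter sets for a recording
#'
#' The two normalizations serve different purposes and want different
#' anchors. The exhale map `[Ac, Fc] -> [0, 1]` spans ambient to face
#' temperature (plume intensities fall between them): `Ac` is the background
#' median, `Fc` the 99th-percentile face count. The tracking map
#' `[Fc, Imax] -> [0, 1]` should expose facial texture for corner detection,
#' so its low anchor is placed partway between ambient and the face level
#' (fraction `track_anchor`), with `Imax` the frame maximum; anchoring at
#' the 99th face percentile would clamp nearly all facial texture to zero.
#'
#' @param frame integer matrix of counts (typically the first frame).
#' @param face_region [roi()] covering the face / nose-mouth window.
#' @param bg_region [roi()] of clean background (optional: falls back to the
#'   25th percentile of the frame).
#' @param track_anchor fraction of the ambient-to-face range at which the
#'   tracking low anchor sits (default 0.3).
#' @return list with `tracking` and `exhale`, both [norm_params()].
#' @export
estimate_norm_params <- function(frame, face_region, bg_region = NULL,
                                 track_anchor = 0.3) {
  Ac <- if (!is.null(bg_region)) estimate_ambient(frame, bg_region)
        else as.numeric(stats::quantile(frame, 0.25))
  Fc <- estimate_face_count(frame, face_region)
  if (Fc <= Ac) stop("face region is not warmer than background")
  Imax <- max(max(frame), Fc + 1)
  list(tracking = norm_params(Fc = Ac + track_anchor * (Fc - Ac), Ac = Ac,
                              Imax = Imax),
       exhale = norm_params(Fc = Fc, Ac = Ac, Imax = Imax))
}

#' Normalize a count frame
#'
#' Two parallel linear normalizations of the same raw frame are used
#' downstream: `"tracking"` maps `[Fc, Imax] -> [0, 1]` to expose stable
#' facial feature points, and `"exhale"` maps `[Ac, Fc] -> [0, 1]` to span
#' the range in which exhaled-plume intensities live. Values outside the
#' interval are clamped to 0/1: the map deliberately targets a sub-range of
#' the observed counts.
#'
#' @param frame numeric/integer matrix of counts.
#' @param params a [norm_params()].
#' @param mode `"tracking"` or `"exhale"`.
#' @return numeric matrix with values in `[0, 1]` and attribute `mode`.
#' @export
normalize_frame <- function(frame, params, mode = c("exhale", "tracking")) {
  mode <- match.arg(mode)
  if (mode == "exhale") {
    lo <- params$Ac; hi <- params$Fc
    if (lo >= hi) stop("degenerate exhale range: Ac >= Fc")
  } else {
    lo <- params$Fc; hi <- params$Imax
    if (lo >= hi) stop("degenerate tracking range: Fc >= Imax")
  }
  out <- (frame - lo) / (hi - lo)
  out[out < 0] <- 0
  out[out > 1] <- 1
  attr(out, "mode") <- mode
  out
}
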