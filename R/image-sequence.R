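#' Grayscale image sequence
#'
#' Container for time-stamped grayscale frames from one camera.  Frames are
#' numeric matrices indexed `[row, col]`; pixel centres sit at integer
#' coordinates with `x` (column) rightward and `y` (row) downward, origin at
#' the top-left pixel (1, 1).
#'
#' @param frames list of numeric matrices, all of identical dimensions.
#' @param frame_rate acquisition rate, Hz.
#' @param timestamps optional sample times in seconds; synthesized from
#'   `frame_rate` when missing.  Must be strictly increasing and uniform.
#' @param bit_depth nominal bit depth of the data (8 or 16).
#' @param camera_id identifier of the acquiring camera.
#' @return An object of class `image_sequence`.
#' @export
image_sequence <- function(frames, frame_rate, timestamps = NULL,
                           bit_depth = 8, camera_id = "cam1") {
  if (!is.list(frames) || length(frames) < 1L)
    stopf("format error: `frames` must be a non-empty list of matrices")
  dims <- vapply(frames, dim, integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1]))
    stopf("format error: frames have mixed dimensions")
  check_scalar(frame_rate, "frame_rate", lower = 0, strict_lower = TRUE)
  n <- length(frames)
  if (is.null(timestamps)) timestamps <- (seq_len(n) - 1) / frame_rate
  if (length(timestamps) != n)
    stopf("format error: %d timestamps for %d frames", length(timestamps), n)
  dt <- diff(timestamps)
  if (n > 1 && (any(dt <= 0) || max(abs(dt - dt[1])) > 1e-9))
    stopf("format error: timestamps must be strictly increasing and uniform")
  structure(list(frames = frames, frame_rate = frame_rate,
                 timestamps = timestamps, bit_depth = bit_depth,
                 camera_id = camera_id),
            class = "image_sequence")
}

#' @export
print.image_sequence <- function(x, ...) {
  d <- dim(x$frames[[1]])
  cat(sprintf("Image sequence '%s': %d frames of %d x %d px, %g Hz, %d-bit\n",
              x$camera_id, length(x$frames), d[2], d[1], x$frame_rate,
              x$bit_depth))
  invisible(x)
}

#' @export
length.image_sequence <- function(x) length(x$frames)
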