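#' Read a multi-page TIFF time series
#'
#' Loads a grayscale multi-page TIFF into a [frame_sequence]. Intensities are
#' kept on their native scale (integer TIFFs come back as their stored
#' integer values; float TIFFs written by [write_tiff_sequence] are restored
#' via the scale factor recorded in their sidecar file). No rescaling
#' to \[0, 1\] is performed: downstream thresholds are relative, but the
#' absolute scale is preserved.
#'
#' @param path path to an existing TIFF file.
#' @param pixel_size_um,frame_interval_s metadata attached to the result.
#' @param t0_index acquisition-start frame (1-based), default 1.
#' @return a [frame_sequence] with T = number of pages.
#' @seealso [write_tiff_sequence()]
#' @export
read_tiff_sequence <- function(path, pixel_size_um = 1, frame_interval_s = 1,
                               t0_index = 1L) {
  if (!file.exists(path))
    stop(sprintf("TIFF file not found: %s", path), call. = FALSE)
  pages <- tiff::readTIFF(path, all = TRUE, info = TRUE)
  if (length(pages) < 1L) stop("TIFF contains no pages", call. = FALSE)
  dims <- vapply(pages, function(p) dim(p)[1:2], integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1]))
    stop("TIFF pages have inconsistent shapes", call. = FALSE)
  scale <- 1
  scale_file <- paste0(path, ".scale.txt")
  if (file.exists(scale_file)) {
    line <- readLines(scale_file, n = 1L)
    m <- regmatches(line, regexec("intensity_scale=([0-9eE.+-]+)",
                                  line))[[1L]]
    if (length(m) == 2L) scale <- as.numeric(m[2L])
  }
  arr <- array(0, dim = c(length(pages), dims[1, 1], dims[2, 1]))
  for (t in seq_along(pages)) {
    p <- pages[[t]]
    # integer TIFFs come back scaled into [0,1]; undo that exactly
    bits <- attr(p, "bits.per.sample")
    mult <- if (is.null(bits) || bits >= 32L) scale else 2^bits - 1
    if (length(dim(p)) == 3L) p <- p[, , 1L]  # collapse replicated gray planes
    arr[t, , ] <- p * mult
  }
  frame_sequence(arr, pixel_size_um, frame_interval_s, t0_index)
}

#' Write a frame sequence as a multi-page TIFF
#'
#' Integer-valued data within the uint8/uint16 range is stored bit-exactly at
#' the matching bit depth. Anything else is stored as 32-bit float scaled by
#' a power of two into \[0, 1\], with the scale factor recorded in a small
#' `<path>.scale.txt` sidecar so [read_tiff_sequence] restores the original
#' values to float32 precision.
#'
#' @param seq a [frame_sequence].
#' @param path output file path; the containing directory must exist.
#' @param dtype `"auto"` (default), `"uint8"`, `"uint16"` or `"float32"`.
#' @return `path`, invisibly.
#' @export
write_tiff_sequence <- function(seq, path,
                                dtype = c("auto", "uint8", "uint16",
                                          "float32")) {
  stopifnot(inherits(seq, "frame_sequence"))
  dtype <- match.arg(dtype)
  dir <- dirname(path)
  if (!dir.exists(dir))
    stop(sprintf("directory does not exist: %s", dir), call. = FALSE)
  x <- seq$data
  if (dtype == "auto") {
    dtype <- if (all(x == round(x)) && max(x) <= 65535) {
      if (max(x) <= 255) "uint8" else "uint16"
    } else "float32"
  }
  pages <- lapply(seq_len(dim(x)[1L]), function(t)
    matrix(x[t, , ], dim(x)[2L], dim(x)[3L]))
  if (dtype == "uint8") {
    tiff::writeTIFF(lapply(pages, function(p) p / 255), path,
                    bits.per.sample = 8L, reduce = FALSE)
  } else if (dtype == "uint16") {
    tiff::writeTIFF(lapply(pages, function(p) p / 65535), path,
                    bits.per.sample = 16L, reduce = FALSE)
  } else {
    # power-of-two scale: the division is exact in binary floating point
    scale <- 2^ceiling(log2(max(x, 1)))
    tiff::writeTIFF(lapply(pages, function(p) p / scale), path,
                    bits.per.sample = 32L, reduce = FALSE)
    writeLines(sprintf("intensity_scale=%.17g", scale),
               paste0(path, ".scale.txt"))
  }
  invisible(path)
}

#' Split a dual-view camera frame into two channels
#'
#' Emission splitters project both indicator channels side by side onto one
#' camera chip; this slices each frame in half along the stated axis.
#'
#' @param raw a [frame_sequence] holding the combined frames.
#' @param layout `"left-right"` (split along width, default) or
#'   `"top-bottom"` (split along height).
#' @return a [channel_pair]; ch1 is the left (or top) half.
#' @export
split_dual_view <- function(raw, layout = c("left-right", "top-bottom")) {
  stopifnot(inherits(raw, "frame_sequence"))
  layout <- match.arg(layout)
  d <- dim(raw$data)
  if (layout == "left-right") {
    if (d[3L] %% 2L != 0L)
      stop("width must be even for a left-right split", call. = FALSE)
    half <- d[3L] %/% 2L
    a <- raw$data[, , seq_len(half), drop = FALSE]
    b <- raw$data[, , half + seq_len(half), drop = FALSE]
  } else {
    if (d[2L] %% 2L != 0L)
      stop("height must be even for a top-bottom split", call. = FALSE)
    half <- d[2L] %/% 2L
    a <- raw$data[, seq_len(half), , drop = FALSE]
    b <- raw$data[, half + seq_len(half), , drop = FALSE]
  }
  mk <- function(arr) frame_sequence(arr, raw$pixel_size_um,
                                     raw$frame_interval_s, raw$t0_index)
  channel_pair(mk(a), mk(b))
}
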