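#' Time-lapse intensity stack
#'
#' A `frame_sequence` is the pipeline's universal currency: a T x H x W array
#' of nonnegative intensities plus the physical metadata needed to interpret
#' it (pixel size and frame interval). Pixel indices follow array storage:
#' `data[t, y, x]` with `y` the row and `x` the column; a pixel's center sits
#' at its integer index.
#'
#' @param data numeric array. Either T x H x W, or a single H x W matrix
#'   (promoted to T = 1). All values must be finite and >= 0.
#' @param pixel_size_um physical pixel edge length in micrometers (> 0).
#' @param frame_interval_s time between consecutive frames in seconds (> 0).
#' @param t0_index integer index (1-based) of the acquisition-start frame.
#' @param nonneg enforce nonnegative intensities (default). Additive
#'   bleaching correction is the one stage allowed to produce small negative
#'   background values; it sets this to `FALSE`.
#' @return An object of class `frame_sequence`.
#' @examples
#' fs <- frame_sequence(array(1, dim = c(5, 16, 16)),
#'                      pixel_size_um = 0.368, frame_interval_s = 0.025)
#' dim(fs)
#' @export
frame_sequence <- function(data, pixel_size_um = 1, frame_interval_s = 1,
                           t0_index = 1L, nonneg = TRUE) {
  if (is.matrix(data)) data <- array(data, dim = c(1L, nrow(data), ncol(data)))
  if (!is.array(data) || length(dim(data)) != 3L)
    stop("`data` must be a T x H x W array or an H x W matrix", call. = FALSE)
  storage.mode(data) <- "double"
  if (any(!is.finite(data)))
    stop("intensities must be finite", call. = FALSE)
  if (nonneg && any(data < 0))
    stop("intensities must be >= 0", call. = FALSE)
  if (!is.numeric(pixel_size_um) || length(pixel_size_um) != 1L ||
      pixel_size_um <= 0)
    stop("`pixel_size_um` must be a single positive number", call. = FALSE)
  if (!is.numeric(frame_interval_s) || length(frame_interval_s) != 1L ||
      frame_interval_s <= 0)
    stop("`frame_interval_s` must be a single positive number", call. = FALSE)
  structure(
    list(data = data,
         pixel_size_um = as.numeric(pixel_size_um),
         frame_interval_s = as.numeric(frame_interval_s),
         t0_index = as.integer(t0_index)),
    class = "frame_sequence")
}

#' @export
dim.frame_sequence <- function(x) dim(x$data)

#' Number of frames in a sequence
#' @param seq a `frame_sequence`.
#' @return integer frame count.
#' @export
n_frames <- function(seq) dim(seq$data)[1L]

#' Extract one frame as an H x W matrix
#' @param seq a `frame_sequence`.
#' @param t frame index (1-based).
#' @return numeric matrix.
#' @export
get_frame <- function(seq, t) {
  stopifnot(t >= 1L, t <= n_frames(seq))
  matrix(seq$data[t, , ], nrow = dim(seq$data)[2L], ncol = dim(seq$data)[3L])
}

#' Replace one frame
#' @param seq a `frame_sequence`.
#' @param t frame index.
#' @param frame H x W matrix.
#' @return the modified sequence.
#' @export
set_frame <- function(seq, t, frame) {
  stopifnot(all(dim(frame) == dim(seq$data)[2:3]))
  seq$data[t, , ] <- frame
  seq
}

#' Build a sequence from a list of frames, inheriting metadata
#' @param frames list of equally sized H x W matrices.
#' @param template `frame_sequence` supplying metadata.
#' @return a `frame_sequence`.
#' @export
frames_to_sequence <- function(frames, template) {
  h <- nrow(frames[[1L]]); w <- ncol(frames[[1L]])
  arr <- array(0, dim = c(length(frames), h, w))
  for (t in seq_along(frames)) arr[t, , ] <- frames[[t]]
  frame_sequence(arr, template$pixel_size_um, template$frame_interval_s,
                 template$t0_index)
}

#' @export
print.frame_sequence <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf(
    "<frame_sequence> %d frame(s), %d x %d px | %.4g um/px, %.4g s/frame\n",
    d[1L], d[2L], d[3L], x$pixel_size_um, x$frame_interval_s))
  cat(sprintf("  intensity range [%.4g, %.4g]\n",
              min(x$data), max(x$data)))
  invisible(x)
}

#' Paired ratiometric channels
#'
#' Holds the two spectrally complementary indicator channels of a ratiometric
#' acquisition. Both must share shape and metadata.
#'
#' @param ch1 `frame_sequence`, the Ca2+-rising indicator channel.
#' @param ch2 `frame_sequence`, the Ca2+-falling indicator channel.
#' @return An object of class `channel_pair`.
#' @export
channel_pair <- function(ch1, ch2) {
  stopifnot(inherits(ch1, "frame_sequence"), inherits(ch2, "frame_sequence"))
  if (!all(dim(ch1$data) == dim(ch2$data)))
    stop("channels must have identical dimensions", call. = FALSE)
  if (ch1$pixel_size_um != ch2$pixel_size_um ||
      ch1$frame_interval_s != ch2$frame_interval_s)
    stop("channels must share metadata", call. = FALSE)
  structure(list(ch1 = ch1, ch2 = ch2), class = "channel_pair")
}

#' @export
print.channel_pair <- function(x, ...) {
  cat("<channel_pair>\n  ch1: "); print(x$ch1)
  cat("  ch2: "); print(x$ch2)
  invisible(x)
}

#' Per-frame instance label stack
#'
#' Integer labels per pixel: 0 = background, k > 0 = cell instance k within
#' that frame. Labels are per-frame; identity across frames comes from
#' tracking, not from the label values.
#'
#' @param labels integer T x H x W array, values >= 0.
#' @return An object of class `label_sequence`.
#' @export
label_sequence <- function(labels) {
  if (is.matrix(labels))
    labels <- array(labels, dim = c(1L, nrow(labels), ncol(labels)))
  stopifnot(is.array(labels), length(dim(labels)) == 3L)
  if (any(labels < 0) || any(labels != round(labels)))
    stop("labels must be nonnegative integers", call. = FALSE)
  storage.mode(labels) <- "integer"
  structure(list(labels = labels), class = "label_sequence")
}
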