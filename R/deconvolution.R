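#' Discretized Gaussian point spread function
#'
#' @param sigma_px standard deviation in pixels (> 0).
#' @param size odd kernel edge length; default covers +/- 3 sigma.
#' @return a `psf` object: an odd-sized nonnegative kernel summing to 1.
#' @export
gaussian_psf <- function(sigma_px, size = NULL) {
  stopifnot(sigma_px > 0)
  if (is.null(size)) size <- 2L * ceiling(3 * sigma_px) + 1L
  if (size %% 2L == 0L) stop("PSF size must be odd", call. = FALSE)
  half <- (size - 1L) / 2L
  g <- exp(-(-half:half)^2 / (2 * sigma_px^2))
  k <- outer(g, g)
  psf(k / sum(k), provenance = sprintf("gaussian(sigma=%g)", sigma_px))
}

#' Point spread function container
#'
#' @param kernel odd-dimension matrix, entries >= 0, summing to 1 (within
#'   1e-9).
#' @param provenance free-text origin tag.
#' @return a `psf` object.
#' @export
psf <- function(kernel, provenance = "user") {
  stopifnot(is.matrix(kernel))
  if (nrow(kernel) %% 2L == 0L || ncol(kernel) %% 2L == 0L)
    stop("PSF dimensions must be odd (centered kernel)", call. = FALSE)
  if (any(kernel < 0)) stop("PSF entries must be >= 0", call. = FALSE)
  if (abs(sum(kernel) - 1) > 1e-9)
    stop("PSF must sum to 1", call. = FALSE)
  structure(list(kernel = kernel, provenance = provenance), class = "psf")
}

#' Read a PSF from a single-page TIFF
#' @param path TIFF path.
#' @return a normalized `psf`.
#' @export
read_psf <- function(path) {
  k <- get_frame(read_tiff_sequence(path), 1L)
  psf(k / sum(k), provenance = path)
}

# 2-D convolution, "same" size, reflective (symmetric) boundary.
# Circular FFT convolution on the reflect-padded image; the pad absorbs the
# wrap-around, and the center crop is the linear convolution we want.
conv2_reflect <- function(img, kernel) {
  kh <- (nrow(kernel) - 1L) / 2L
  kw <- (ncol(kernel) - 1L) / 2L
  h <- nrow(img); w <- ncol(img)
  if (kh >= h || kw >= w)
    stop("PSF must be smaller than the frame", call. = FALSE)
  ry <- c(rev(seq_len(kh)), seq_len(h), h + 1L - seq_len(kh))
  rx <- c(rev(seq_len(kw)), seq_len(w), w + 1L - seq_len(kw))
  P <- img[ry, rx, drop = FALSE]
  H <- nrow(P); W <- ncol(P)
  K <- matrix(0, H, W)
  for (dy in -kh:kh) for (dx in -kw:kw)
    K[(dy %% H) + 1L, (dx %% W) + 1L] <- kernel[dy + kh + 1L, dx + kw + 1L]
  out <- Re(stats::fft(stats::fft(P) * stats::fft(K), inverse = TRUE)) /
    (H * W)
  out[kh + seq_len(h), kw + seq_len(w), drop = FALSE]
}

#' Lucy-Richardson deconvolution
#'
#' Per-frame multiplicative Richardson-Lucy restoration:
#' `u <- u * conv(flip(psf), d / conv(psf, u))`, initialized at the observed
#' frame `d`. Boundaries are handled by reflective padding, which conserves
#' total intensity for compactly supported objects. Pixels where the blurred
#' estimate falls at or below `eps` receive ratio 1 (no update), so the
#' iteration never divides by zero and never produces negatives.
#'
#' @param seq nonnegative [frame_sequence].
#' @param psf a `psf` (see [gaussian_psf], [read_psf]).
#' @param n_iter number of iterations (>= 1), default 10.
#' @param eps denominator guard, default 1e-12.
#' @return restored [frame_sequence].
#' @export
lucy_richardson <- function(seq, psf, n_iter = 10L, eps = 1e-12) {
  stopifnot(inherits(seq, "frame_sequence"), n_iter >= 1L)
  if (!inherits(psf, "psf"))
    stop("`psf` must be a psf object (normalized kernel)", call. = FALSE)
  k <- psf$kernel
  kf <- k[nrow(k):1, ncol(k):1, drop = FALSE]
  frames <- lapply(seq_len(n_frames(seq)), function(t) {
    d <- get_frame(seq, t)
    u <- d
    for (i in seq_len(n_iter)) {
      blur <- conv2_reflect(u, k)
      ratio <- matrix(1, nrow(d), ncol(d))
      ok <- blur > eps
      ratio[ok] <- d[ok] / blur[ok]
      u <- u * conv2_reflect(ratio, kf)
      u[u < 0] <- 0  # clamp FFT round-off
    }
    u
  })
  frames_to_sequence(frames, seq)
}
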