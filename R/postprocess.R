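#' 2-D affine transform
#'
#' Maps moving-image pixel coordinates into fixed-image coordinates:
#' `p_fixed = matrix %*% p_moving + offset`, with `p = (y, x)` in pixels.
#'
#' @param matrix 2 x 2 real matrix, invertible.
#' @param offset length-2 numeric `(dy, dx)`.
#' @return An object of class `affine_transform2d`.
#' @export
affine_transform2d <- function(matrix = diag(2), offset = c(0, 0)) {
  matrix <- base::matrix(as.numeric(matrix), 2L, 2L)
  if (abs(det(matrix)) <= 1e-9)
    stop("affine matrix is singular", call. = FALSE)
  structure(list(matrix = matrix, offset = as.numeric(offset)),
            class = "affine_transform2d")
}

#' @export
print.affine_transform2d <- function(x, ...) {
  cat("<affine_transform2d>\n  matrix:\n")
  print(x$matrix)
  cat(sprintf("  offset (dy, dx): %.4f, %.4f\n", x$offset[1], x$offset[2]))
  invisible(x)
}

# Sample `frame` at real-valued (y, x) positions; out-of-domain -> fill.
sample_frame <- function(frame, ys, xs,
                         interpolation = c("linear", "nearest"), fill = 0) {
  interpolation <- match.arg(interpolation)
  h <- nrow(frame); w <- ncol(frame)
  out <- rep(fill, length(ys))
  if (interpolation == "nearest") {
    yi <- round(ys); xi <- round(xs)
    ok <- yi >= 1 & yi <= h & xi >= 1 & xi <= w
    out[ok] <- frame[cbind(yi[ok], xi[ok])]
  } else {
    y0 <- floor(ys); x0 <- floor(xs)
    fy <- ys - y0; fx <- xs - x0
    ok <- y0 >= 1 & y0 + 1 <= h & x0 >= 1 & x0 + 1 <= w
    if (any(ok)) {
      y0k <- y0[ok]; x0k <- x0[ok]; fyk <- fy[ok]; fxk <- fx[ok]
      v00 <- frame[cbind(y0k, x0k)]
      v01 <- frame[cbind(y0k, x0k + 1)]
      v10 <- frame[cbind(y0k + 1, x0k)]
      v11 <- frame[cbind(y0k + 1, x0k + 1)]
      out[ok] <- v00 * (1 - fyk) * (1 - fxk) + v01 * (1 - fyk) * fxk +
        v10 * fyk * (1 - fxk) + v11 * fyk * fxk
    }
    # exact grid points on the last row/column
    edge <- !ok & ys >= 1 & ys <= h & xs >= 1 & xs <= w &
      abs(ys - round(ys)) < 1e-9 & abs(xs - round(xs)) < 1e-9
    if (any(edge))
      out[edge] <- frame[cbind(round(ys[edge]), round(xs[edge]))]
  }
  out
}

# Resample `moving` onto the fixed grid under `tf` (moving -> fixed coords).
warp_frame <- function(moving, tf, interpolation = "linear") {
  h <- nrow(moving); w <- ncol(moving)
  inv <- solve(tf$matrix)
  grid <- expand.grid(y = seq_len(h), x = seq_len(w))
  p <- inv %*% rbind(grid$y - tf$offset[1], grid$x - tf$offset[2])
  matrix(sample_frame(moving, p[1, ], p[2, ], interpolation), h, w)
}

ncc <- function(a, b) {
  a <- a - mean(a); b <- b - mean(b)
  den <- sqrt(sum(a^2) * sum(b^2))
  if (den <= 0) return(0)
  sum(a * b) / den
}

# Integer-shift initialization by regularized phase correlation. The
# spectral whitening is damped so that smooth, band-limited images (whose
# high frequencies are numerically empty) still give a clean peak.
phase_correlation_shift <- function(fixed, moving) {
  fa <- stats::fft(fixed - mean(fixed))
  fb <- stats::fft(moving - mean(moving))
  cp <- fa * Conj(fb)
  mag <- Mod(cp)
  r <- Re(stats::fft(cp / (mag + 0.01 * max(mag)), inverse = TRUE))
  idx <- which(r == max(r), arr.ind = TRUE)[1, ]
  s <- idx - 1L
  h <- nrow(fixed); w <- ncol(fixed)
  if (s[1] > h / 2) s[1] <- s[1] - h
  if (s[2] > w / 2) s[2] <- s[2] - w
  as.numeric(s)  # offset (dy, dx) such that moving(p - s) ~ fixed(p)
}

#' Register one channel frame onto another
#'
#' Intensity-based alignment of two simultaneously acquired indicator
#' channels: phase correlation provides an integer-pixel translation start,
#' which is refined by maximizing normalized cross-correlation, first over
#' translation only and then (optionally) over a full affine matrix.
#'
#' @param fixed,moving equally sized nonconstant matrices (single frames).
#' @param mode `"affine"` (default) or `"translation"`.
#' @return an [affine_transform2d] mapping moving coordinates into fixed
#'   coordinates; applying it with [apply_transform] resamples the moving
#'   channel onto the fixed channel's grid.
#' @export
register_channels <- function(fixed, moving, mode = c("affine",
                                                      "translation")) {
  mode <- match.arg(mode)
  stopifnot(is.matrix(fixed), is.matrix(moving),
            all(dim(fixed) == dim(moving)))
  if (stats::sd(fixed) == 0 || stats::sd(moving) == 0)
    stop("cannot register constant images", call. = FALSE)
  init <- phase_correlation_shift(fixed, moving)
  obj_t <- function(p) {
    tf <- affine_transform2d(diag(2), p)
    -ncc(fixed, warp_frame(moving, tf))
  }
  # multi-start: phase-correlation peak plus the no-shift hypothesis
  starts <- unique(list(init, c(0, 0)))
  opts <- lapply(starts, function(s)
    stats::optim(s, obj_t, method = "Nelder-Mead",
                 control = list(maxit = 200, reltol = 1e-10)))
  opt_t <- opts[[which.min(vapply(opts, function(o) o$value, 0))]]
  if (mode == "translation")
    return(affine_transform2d(diag(2), opt_t$par))
  # affine refinement parameterized about the image center: the matrix acts
  # on centered coordinates, so its entries decouple from the translation
  ctr <- (dim(fixed) + 1) / 2
  centered_tf <- function(p) {
    A <- matrix(p[1:4], 2, 2)
    affine_transform2d(A, ctr + p[5:6] - A %*% ctr)
  }
  obj_a <- function(p) {
    tf <- tryCatch(centered_tf(p), error = function(e) NULL)
    if (is.null(tf)) return(1)
    -ncc(fixed, warp_frame(moving, tf))
  }
  p0 <- c(1, 0, 0, 1, opt_t$par)
  opt_a <- stats::optim(p0, obj_a, method = "Nelder-Mead",
                        control = list(maxit = 1000, reltol = 1e-12,
                                       parscale = c(rep(0.01, 4), 0.5, 0.5)))
  if (opt_a$value <= opt_t$value)
    centered_tf(opt_a$par)
  else
    affine_transform2d(diag(2), opt_t$par)
}

#' Resample a sequence under an affine transform
#'
#' @param seq a [frame_sequence] (the moving channel).
#' @param tf an [affine_transform2d], or a list of one per frame when
#'   `mode = "per-frame"`.
#' @param mode `"first-frame"` applies one transform to every frame
#'   (default); `"per-frame"` expects a transform list of length T.
#' @param interpolation `"linear"` (default) or `"nearest"`.
#' @return resampled [frame_sequence], same shape; out-of-domain pixels 0.
#' @export
apply_transform <- function(seq, tf, mode = c("first-frame", "per-frame"),
                            interpolation = c("linear", "nearest")) {
  mode <- match.arg(mode)
  interpolation <- match.arg(interpolation)
  stopifnot(inherits(seq, "frame_sequence"))
  nt <- n_frames(seq)
  if (mode == "first-frame") {
    stopifnot(inherits(tf, "affine_transform2d"))
    tfs <- rep(list(tf), nt)
  } else {
    if (!is.list(tf) || length(tf) != nt)
      stop(sprintf("per-frame mode needs a list of %d transforms", nt),
           call. = FALSE)
    tfs <- tf
  }
  frames <- lapply(seq_len(nt), function(t)
    warp_frame(get_frame(seq, t), tfs[[t]], interpolation))
  frames_to_sequence(frames, seq)
}

#' Estimate per-frame background level
#'
#' @param seq a [frame_sequence].
#' @param method `"percentile"` (default: a low percentile of each frame's
#'   pixels), `"roi"` (mean over a fixed rectangle), or `"constant"`.
#' @param percentile percentile in \[0, 100\] for the percentile method.
#' @param roi `c(y0, y1, x0, x1)` rectangle for the roi method.
#' @param value fixed level for the constant method.
#' @return numeric vector, one background level per frame.
#' @export
estimate_background <- function(seq, method = c("percentile", "roi",
                                                "constant"),
                                percentile = 1, roi = NULL, value = 0) {
  method <- match.arg(method)
  stopifnot(inherits(seq, "frame_sequence"))
  nt <- n_frames(seq)
  switch(method,
    percentile = vapply(seq_len(nt), function(t)
      as.numeric(stats::quantile(get_frame(seq, t), percentile / 100,
                                 type = 1)), 0),
    roi = {
      stopifnot(length(roi) == 4L)
      vapply(seq_len(nt), function(t)
        mean(get_frame(seq, t)[roi[1]:roi[2], roi[3]:roi[4]]), 0)
    },
    constant = rep(as.numeric(value), nt))
}

#' Subtract background fluorescence
#'
#' `output = max(input - bg, 0)` elementwise, clipped at zero.
#'
#' @param seq a [frame_sequence].
#' @param bg nonnegative scalar or per-frame vector of length T.
#' @return corrected [frame_sequence]; never negative.
#' @export
subtract_background <- function(seq, bg) {
  stopifnot(inherits(seq, "frame_sequence"))
  nt <- n_frames(seq)
  if (any(bg < 0)) stop("background must be >= 0", call. = FALSE)
  if (length(bg) == 1L) bg <- rep(bg, nt)
  if (length(bg) != nt)
    stop("`bg` must be a scalar or one value per frame", call. = FALSE)
  out <- seq$data
  for (t in seq_len(nt)) out[t, , ] <- pmax(out[t, , ] - bg[t], 0)
  frame_sequence(out, seq$pixel_size_um, seq$frame_interval_s, seq$t0_index)
}

#' Compute the ratiometric image
#'
#' Elementwise ch1/ch2 (or the reverse). Pixels whose denominator is at or
#' below `eps` are set to 0 rather than NaN/Inf — a zero can never become a
#' microdomain because detection thresholds exceed 1 x the cell mean.
#'
#' @param pair a [channel_pair] with aligned channels.
#' @param clip optional `c(lo, hi)`; values outside are set to the bound.
#' @param orientation `"ch1/ch2"` (default) or `"ch2/ch1"`.
#' @param eps denominator guard, default 1e-12.
#' @return ratio [frame_sequence]; contains no non-finite values.
#' @export
compute_ratio <- function(pair, clip = NULL,
                          orientation = c("ch1/ch2", "ch2/ch1"),
                          eps = 1e-12) {
  stopifnot(inherits(pair, "channel_pair"))
  orientation <- match.arg(orientation)
  num <- pair$ch1$data; den <- pair$ch2$data
  if (orientation == "ch2/ch1") { tmp <- num; num <- den; den <- tmp }
  r <- array(0, dim = dim(num))
  ok <- den > eps
  r[ok] <- num[ok] / den[ok]
  if (!is.null(clip)) {
    stopifnot(length(clip) == 2L, clip[1] < clip[2])
    r[r < clip[1]] <- clip[1]
    r[r > clip[2]] <- clip[2]
  }
  frame_sequence(r, pair$ch1$pixel_size_um, pair$ch1$frame_interval_s,
                 pair$ch1$t0_index)
}

# masks: logical T x H x W array or list of H x W logicals.
as_mask_list <- function(masks, nt) {
  if (is.list(masks)) {
    stopifnot(length(masks) == nt)
    lapply(masks, function(m) m != 0)
  } else if (is.array(masks) && length(dim(masks)) == 3L) {
    stopifnot(dim(masks)[1L] == nt)
    lapply(seq_len(nt), function(t)
      matrix(masks[t, , ] != 0, dim(masks)[2L], dim(masks)[3L]))
  } else if (is.matrix(masks)) {
    rep(list(masks != 0), nt)
  } else stop("`masks` must be a matrix, list of matrices, or TxHxW array",
              call. = FALSE)
}

masked_means <- function(seq, mask_list) {
  vapply(seq_len(n_frames(seq)), function(t) {
    m <- mask_list[[t]]
    if (!any(m))
      stop(sprintf("empty cell mask in frame %d", t), call. = FALSE)
    mean(get_frame(seq, t)[m])
  }, 0)
}

#' Additive frame-wise bleaching correction
#'
#' Adds a per-frame offset so the mean intensity over the cell mask is the
#' same constant in every frame. Intended for the indicator channel that
#' bleaches (the offset is applied to all pixels, so background values may
#' go slightly negative).
#'
#' @param seq a [frame_sequence].
#' @param masks per-frame cell masks: logical T x H x W array, list of H x W
#'   logical matrices, or one matrix reused for all frames. Every frame's
#'   mask must be nonempty.
#' @param target_mean the constant to normalize to; defaults to the first
#'   frame's masked mean.
#' @return corrected [frame_sequence] whose masked mean is `target_mean` in
#'   every frame (to float precision).
#' @export
correct_bleaching_additive <- function(seq, masks, target_mean = NULL) {
  stopifnot(inherits(seq, "frame_sequence"))
  ml <- as_mask_list(masks, n_frames(seq))
  mm <- masked_means(seq, ml)
  if (is.null(target_mean)) target_mean <- mm[1L]
  stopifnot(target_mean > 0)
  out <- seq$data
  for (t in seq_len(n_frames(seq)))
    out[t, , ] <- out[t, , ] + (target_mean - mm[t])
  frame_sequence(out, seq$pixel_size_um, seq$frame_interval_s, seq$t0_index,
                 nonneg = FALSE)
}

#' Multiplicative frame-wise bleaching correction
#'
#' Scales each frame by `target_mean / masked_mean(t)`.
#'
#' @inheritParams correct_bleaching_additive
#' @return corrected [frame_sequence].
#' @export
correct_bleaching_multiplicative <- function(seq, masks, target_mean = NULL) {
  stopifnot(inherits(seq, "frame_sequence"))
  ml <- as_mask_list(masks, n_frames(seq))
  mm <- masked_means(seq, ml)
  if (any(mm <= 0))
    stop("multiplicative correction needs positive masked means",
         call. = FALSE)
  if (is.null(target_mean)) target_mean <- mm[1L]
  stopifnot(target_mean > 0)
  out <- seq$data
  for (t in seq_len(n_frames(seq)))
    out[t, , ] <- out[t, , ] * (target_mean / mm[t])
  frame_sequence(out, seq$pixel_size_um, seq$frame_interval_s, seq$t0_index)
}

#' Fit a biexponential bleaching model to a mean-intensity trace
#'
#' Fits `f(t) = a + b1*exp(-t/tau1) + b2*exp(-t/tau2)` by
#' Levenberg-Marquardt least squares with positivity constraints on the
#' decay constants. The two exponential terms are exchangeable; the fit is
#' reported with `tau1 <= tau2`.
#'
#' @param mean_trace per-frame masked mean intensities (length >= 6).
#' @param times acquisition times in seconds, strictly increasing; defaults
#'   to `0, 1, 2, ...`.
#' @return a `bleach_model` list with elements `kind = "biexponential"`,
#'   `a`, `b1`, `tau1`, `b2`, `tau2`, `residual_norm` and `fitted(t)`.
#' @export
fit_biexponential <- function(mean_trace, times = NULL) {
  y <- as.numeric(mean_trace)
  n <- length(y)
  if (n < 6L) stop("need at least 6 points to fit", call. = FALSE)
  if (is.null(times)) times <- seq_len(n) - 1
  if (any(diff(times) <= 0))
    stop("times must be strictly increasing", call. = FALSE)
  span <- diff(range(times))
  model <- function(p, t) p[1] + p[2] * exp(-t / p[3]) + p[4] * exp(-t / p[5])
  if (stats::sd(y) < 1e-12 * max(abs(mean(y)), 1)) {
    p <- c(mean(y), 0, span / 4, 0, span)
  } else {
    amp <- y[1] - y[n]
    starts <- list(
      c(y[n], amp / 2, span / 10, amp / 2, span / 2),
      c(y[n], amp * 0.8, span / 20, amp * 0.2, span),
      c(y[n], amp * 0.2, span / 5, amp * 0.8, span * 2))
    best <- NULL
    for (s in starts) {
      fit <- tryCatch(
        minpack.lm::nls.lm(
          par = s,
          fn = function(p) y - model(p, times),
          lower = c(-Inf, -Inf, 1e-6, -Inf, 1e-6),
          control = minpack.lm::nls.lm.control(maxiter = 400)),
        error = function(e) NULL)
      if (!is.null(fit)) {
        rn <- sqrt(sum(fit$fvec^2))
        if (is.null(best) || rn < best$rn) best <- list(p = fit$par, rn = rn)
      }
    }
    if (is.null(best))
      stop("biexponential fit did not converge; consider the frame-wise ",
           "additive correction instead", call. = FALSE)
    p <- best$p
  }
  if (p[3] > p[5]) p <- p[c(1, 4, 5, 2, 3)]  # enforce tau1 <= tau2
  structure(
    list(kind = "biexponential",
         a = p[1], b1 = p[2], tau1 = p[3], b2 = p[4], tau2 = p[5],
         residual_norm = sqrt(sum((y - model(p, times))^2)),
         fitted = function(t) model(p, t)),
    class = "bleach_model")
}

#' @export
print.bleach_model <- function(x, ...) {
  cat(sprintf(
    "<bleach_model> %s: a=%.4g b1=%.4g tau1=%.4g b2=%.4g tau2=%.4g (rss^0.5=%.3g)\n",
    x$kind, x$a, x$b1, x$tau1, x$b2, x$tau2, x$residual_norm))
  invisible(x)
}

#' Biexponential-fit additive bleaching correction
#'
#' Fits the biexponential decay to the masked mean trace and subtracts the
#' fitted drift `f(t) - f(0)` from every pixel of frame t, so the corrected
#' mean trace is flat at its initial value.
#'
#' @inheritParams correct_bleaching_additive
#' @param times acquisition times (seconds); defaults to
#'   `(0:(T-1)) * frame_interval_s`.
#' @return list with `seq` (corrected [frame_sequence]) and `model`
#'   (the fitted `bleach_model`).
#' @export
correct_bleaching_biexponential <- function(seq, masks, times = NULL) {
  stopifnot(inherits(seq, "frame_sequence"))
  ml <- as_mask_list(masks, n_frames(seq))
  mm <- masked_means(seq, ml)
  if (is.null(times)) times <- (seq_len(n_frames(seq)) - 1) *
      seq$frame_interval_s
  model <- fit_biexponential(mm, times)
  drift <- model$fitted(times) - model$fitted(times[1L])
  out <- seq$data
  for (t in seq_len(n_frames(seq))) out[t, , ] <- out[t, , ] - drift[t]
  list(seq = frame_sequence(out, seq$pixel_size_um, seq$frame_interval_s,
                            seq$t0_index, nonneg = FALSE),
       model = model)
}
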