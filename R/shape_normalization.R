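#' Convert a boundary polyline to a polar outline
#'
#' The cell centroid becomes the origin of a polar coordinate system; each
#' boundary vertex is recorded as `(r_o, theta)`. Angles are measured
#' counterclockwise from the +x (column) axis with "up" meaning decreasing
#' row index, matching the clock convention used for bead contacts
#' ([clock_to_angle]). `r_av` is the arithmetic mean of the boundary radii.
#'
#' @param boundary closed polyline, n x 2 matrix of `(y, x)` vertices.
#' @param centroid `(y, x)` point strictly inside the boundary.
#' @return a `polar_outline`: `origin`, `theta` (sorted, \[0, 2pi)), `r_o`,
#'   `r_av`, `n`.
#' @export
outline_to_polar <- function(boundary, centroid) {
  boundary <- matrix(boundary, ncol = 2)
  n <- nrow(boundary)
  if (n < 8L) stop("boundary needs at least 8 vertices", call. = FALSE)
  if (!pracma::inpolygon(centroid[2], centroid[1],
                         boundary[, 2], boundary[, 1]))
    stop("centroid lies outside the boundary polygon", call. = FALSE)
  dx <- boundary[, 2] - centroid[2]
  dy_up <- centroid[1] - boundary[, 1]
  r <- sqrt(dx^2 + dy_up^2)
  if (any(r <= 0))
    stop("boundary vertex coincides with the centroid", call. = FALSE)
  th <- atan2(dy_up, dx) %% (2 * pi)
  ord <- order(th)
  th <- th[ord]; r <- r[ord]
  gaps <- diff(c(th, th[1L] + 2 * pi))
  if (max(gaps) >= pi / 2)
    stop("boundary does not cover the full angular range ",
         "(largest gap >= pi/2); is the centroid inside?", call. = FALSE)
  # non-star-convex outlines fold back in angle; keep the outermost radius
  dup <- duplicated(th)
  if (any(dup)) {
    keep <- !logical(length(th))
    for (i in which(dup)) {
      j <- which(th == th[i])
      keep[j[-which.max(r[j])]] <- FALSE
    }
    th <- th[keep]; r <- r[keep]
  }
  structure(list(origin = as.numeric(centroid), theta = th, r_o = r,
                 r_av = mean(r), n = length(r)),
            class = "polar_outline")
}

#' @export
print.polar_outline <- function(x, ...) {
  cat(sprintf(
    "<polar_outline> %d samples about (%.2f, %.2f), r_av = %.3f px\n",
    x$n, x$origin[1], x$origin[2], x$r_av))
  invisible(x)
}

# Radius of the outline at query angles, by nearest sampled boundary angle.
outline_radius_at <- function(outline, theta_q) {
  th <- outline$theta; r <- outline$r_o; n <- length(th)
  theta_q <- theta_q %% (2 * pi)
  # circular nearest neighbour over the sorted angle grid
  pos <- findInterval(theta_q, th)
  lo <- ifelse(pos == 0L, n, pos)
  hi <- ifelse(pos == n, 1L, pos + 1L)
  d_lo <- abs(theta_q - th[lo]); d_lo <- pmin(d_lo, 2 * pi - d_lo)
  d_hi <- abs(theta_q - th[hi]); d_hi <- pmin(d_hi, 2 * pi - d_hi)
  ifelse(d_lo <= d_hi, r[lo], r[hi])
}

#' Map one cell frame onto the circular template
#'
#' Radial shape normalization: the boundary point at angle theta, at radius
#' `r_o(theta)`, is sent to radius `c_factor * r_av` (or a caller-supplied
#' fixed template radius), linearly in r and leaving theta unchanged. The
#' output is built by the inverse map with nearest-neighbor sampling: each
#' template pixel at polar `(r', theta)` takes the source value at
#' `r = r' * r_o(theta) / R_template`. Pixels outside the template disk are
#' set to 0; the normalized mask is exactly that disk.
#'
#' @param frame H x W intensity matrix.
#' @param mask logical H x W cell mask (used only for reporting; sampling
#'   follows the outline).
#' @param outline a `polar_outline` for this frame.
#' @param c_factor constant scale applied to `r_av` (default 1).
#' @param template_radius optional fixed template radius in px; overrides
#'   `c_factor * r_av` (used by [normalize_trace] to share one template
#'   across frames).
#' @return list with `image` (normalized frame) and `mask` (template disk).
#' @export
normalize_frame <- function(frame, mask, outline, c_factor = 1,
                            template_radius = NULL) {
  stopifnot(is.matrix(frame), inherits(outline, "polar_outline"))
  R_t <- if (is.null(template_radius)) c_factor * outline$r_av
         else template_radius
  stopifnot(R_t > 0)
  h <- nrow(frame); w <- ncol(frame)
  cy <- outline$origin[1]; cx <- outline$origin[2]
  grid <- expand.grid(y = seq_len(h), x = seq_len(w))
  dx <- grid$x - cx; dy_up <- cy - grid$y
  rp <- sqrt(dx^2 + dy_up^2)
  th <- atan2(dy_up, dx) %% (2 * pi)
  inside <- rp <= R_t
  out <- numeric(h * w)
  if (any(inside)) {
    ro <- outline_radius_at(outline, th[inside])
    r_src <- rp[inside] * ro / R_t
    ys <- cy - r_src * sin(th[inside])
    xs <- cx + r_src * cos(th[inside])
    out[inside] <- sample_frame(frame, ys, xs, interpolation = "nearest")
  }
  list(image = matrix(out, h, w),
       mask = matrix(inside, h, w))
}

#' Shape-normalize a whole cell trace
#'
#' Applies [normalize_frame] to every frame, with a single template radius
#' `c_factor * median(r_av)` over the trace so that all frames share one
#' template circle and temporal dynamics stay comparable.
#'
#' @param trace a `cell_trace` from [extract_roi].
#' @param c_factor constant scale applied to the trace-median `r_av`.
#' @return a `cell_trace` whose `roi` holds the normalized frames, whose
#'   masks are the template disk, and which carries `template_radius` and
#'   per-frame `outlines`.
#' @export
normalize_trace <- function(trace, c_factor = 1) {
  stopifnot(inherits(trace, "cell_trace"))
  nt <- length(trace$frames)
  outlines <- vector("list", nt)
  for (i in seq_len(nt)) {
    idx <- which(trace$masks[[i]], arr.ind = TRUE)
    centroid <- c(mean(idx[, 1]), mean(idx[, 2]))
    outlines[[i]] <- outline_to_polar(trace$boundaries[[i]], centroid)
  }
  r_av <- vapply(outlines, function(o) o$r_av, 0)
  R_t <- c_factor * stats::median(r_av)
  frames <- vector("list", nt); masks <- vector("list", nt)
  bnds <- vector("list", nt)
  phi <- seq(0, 2 * pi, length.out = 91L)[-91L]
  for (i in seq_len(nt)) {
    nf <- tryCatch(
      normalize_frame(get_frame(trace$roi, i), trace$masks[[i]],
                      outlines[[i]], template_radius = R_t),
      error = function(e)
        stop(sprintf("shape normalization failed in frame %d: %s",
                     trace$frames[i], conditionMessage(e)), call. = FALSE))
    frames[[i]] <- nf$image
    masks[[i]] <- nf$mask
    o <- outlines[[i]]$origin
    bnds[[i]] <- cbind(y = o[1] - R_t * sin(phi), x = o[2] + R_t * cos(phi))
  }
  out <- trace
  out$roi <- frames_to_sequence(frames, trace$roi)
  out$masks <- masks
  out$boundaries <- bnds
  out$outlines <- outlines
  out$template_radius <- R_t
  out
}
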