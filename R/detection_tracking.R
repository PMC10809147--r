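#' Segment one frame into cell instances
#'
#' Default classical backend: Gaussian smoothing, Otsu threshold, hole
#' filling, watershed split on the distance transform, then a minimum-area
#' filter. Any function mapping a frame matrix to an integer label matrix
#' can be plugged in instead (e.g. an adapter around a pretrained deep
#' segmentation model).
#'
#' @param frame H x W intensity matrix.
#' @param backend `"threshold"` (default) or a function
#'   `frame -> integer label matrix`.
#' @param min_area_px discard objects smaller than this (default 30).
#' @param smooth_sigma Gaussian pre-smoothing sigma in px (default 1).
#' @param watershed_tolerance minimum object-separation depth for the
#'   distance-transform watershed (default 1).
#' @return list of `cell_detection` objects, each with `frame` (NA until
#'   assigned), `label`, `centroid` `(y, x)`, `area_px`, logical `mask`, and
#'   `boundary` (closed polyline, n x 2 of `(y, x)`). A constant frame
#'   yields an empty list.
#' @export
segment_frame <- function(frame, backend = "threshold", min_area_px = 30L,
                          smooth_sigma = 1, watershed_tolerance = 1) {
  stopifnot(is.matrix(frame))
  if (is.function(backend)) {
    labels <- backend(frame)
  } else {
    if (stats::sd(frame) == 0) return(list())
    rng <- range(frame)
    norm <- (frame - rng[1]) / (rng[2] - rng[1])
    sm <- EBImage::gblur(norm, sigma = smooth_sigma)
    sm[sm < 0] <- 0; sm[sm > 1] <- 1
    bw <- sm > EBImage::otsu(sm, range = c(0, 1))
    bw <- EBImage::fillHull(bw)
    dm <- EBImage::distmap(bw)
    labels <- EBImage::watershed(dm, tolerance = watershed_tolerance)
  }
  labels <- matrix(as.integer(labels), nrow(frame), ncol(frame))
  detections_from_labels(labels, min_area_px)
}

detections_from_labels <- function(labels, min_area_px = 0L) {
  out <- list()
  contours <- EBImage::ocontour(labels)
  for (k in seq_len(max(labels, 0L))) {
    mask <- labels == k
    area <- sum(mask)
    if (area == 0L || area < min_area_px) next
    idx <- which(mask, arr.ind = TRUE)
    centroid <- c(mean(idx[, 1]), mean(idx[, 2]))
    bnd <- contours[[k]] + 1  # ocontour is 0-based (dim1, dim2) = (y, x)
    out[[length(out) + 1L]] <- structure(
      list(frame = NA_integer_, label = k, centroid = centroid,
           area_px = area, mask = mask,
           boundary = matrix(bnd, ncol = 2,
                             dimnames = list(NULL, c("y", "x")))),
      class = "cell_detection")
  }
  out
}

#' Segment every frame of a sequence
#'
#' @param seq a [frame_sequence].
#' @param ... passed to [segment_frame].
#' @return list of length T; element t holds the `cell_detection`s of frame
#'   t with their `frame` field set.
#' @export
segment_sequence <- function(seq, ...) {
  stopifnot(inherits(seq, "frame_sequence"))
  lapply(seq_len(n_frames(seq)), function(t) {
    dets <- segment_frame(get_frame(seq, t), ...)
    lapply(dets, function(d) { d$frame <- t; d })
  })
}

# Optimal gated bipartite matching between two point sets.
# Returns an integer vector: for each row i, the matched column or NA.
match_points <- function(from, to, max_disp) {
  n1 <- nrow(from); n2 <- nrow(to)
  if (n1 == 0L || n2 == 0L) return(rep(NA_integer_, n1))
  d <- sqrt(outer(from[, 1], to[, 1], "-")^2 +
            outer(from[, 2], to[, 2], "-")^2)
  big <- (max(d) + max_disp + 1) * (n1 + n2)  # forbidden / dummy cost
  n <- max(n1, n2)
  cost <- matrix(big, n, n)
  cost[seq_len(n1), seq_len(n2)] <- ifelse(d <= max_disp, d, big)
  sol <- as.integer(clue::solve_LSAP(cost))
  res <- rep(NA_integer_, n1)
  for (i in seq_len(n1)) {
    j <- sol[i]
    if (j <= n2 && cost[i, j] < big) res[i] <- j
  }
  res
}

#' Link per-frame detections into cell tracks
#'
#' Consecutive-frame assignments are solved as optimal bipartite matchings
#' on centroid distance (Hungarian method), gated at `max_disp`. Tracks that
#' disappear may be bridged across up to `max_gap` missing frames; tracks
#' with fewer than `min_frames` detections are dropped.
#'
#' @param detections list (length T) of per-frame `cell_detection` lists, as
#'   produced by [segment_sequence].
#' @param max_disp maximum allowed centroid displacement between linked
#'   detections, in px.
#' @param min_frames minimum number of detections per retained track.
#' @param max_gap maximum number of consecutive missing frames bridged.
#' @return list of `track` objects: `id`, `detections` (frame-ordered),
#'   `frame_span`.
#' @export
link_tracks <- function(detections, max_disp, min_frames = 1L,
                        max_gap = 2L) {
  stopifnot(max_disp > 0, min_frames >= 1L)
  active <- list()   # each: list(id, dets, last_frame, last_centroid)
  done <- list()
  next_id <- 1L
  for (t in seq_along(detections)) {
    dets <- detections[[t]]
    # retire tracks that can no longer be continued
    if (length(active)) {
      keep <- vapply(active, function(tr) t - tr$last_frame <= max_gap + 1L,
                     TRUE)
      done <- c(done, active[!keep])
      active <- active[keep]
    }
    if (length(dets) == 0L) next
    cent <- t(vapply(dets, function(d) d$centroid, numeric(2)))
    assigned <- rep(FALSE, length(dets))
    if (length(active)) {
      last <- t(vapply(active, function(tr) tr$last_centroid, numeric(2)))
      m <- match_points(last, cent, max_disp)
      for (i in seq_along(active)) {
        j <- m[i]
        if (!is.na(j)) {
          d <- dets[[j]]; d$frame <- t
          active[[i]]$dets <- c(active[[i]]$dets, list(d))
          active[[i]]$last_frame <- t
          active[[i]]$last_centroid <- d$centroid
          assigned[j] <- TRUE
        }
      }
    }
    for (j in which(!assigned)) {
      d <- dets[[j]]; d$frame <- t
      active[[length(active) + 1L]] <- list(id = next_id, dets = list(d),
                                            last_frame = t,
                                            last_centroid = d$centroid)
      next_id <- next_id + 1L
    }
  }
  done <- c(done, active)
  tracks <- lapply(done, function(tr) {
    frames <- vapply(tr$dets, function(d) d$frame, 0L)
    structure(list(id = tr$id, detections = tr$dets,
                   frame_span = c(frames[1L], frames[length(frames)])),
              class = "track")
  })
  tracks <- Filter(function(tr) length(tr$detections) >= min_frames, tracks)
  # stable ordering by first frame then id
  ord <- order(vapply(tracks, function(tr) tr$frame_span[1L], 0L),
               vapply(tracks, function(tr) tr$id, 0L))
  tracks[ord]
}

#' @export
print.track <- function(x, ...) {
  cat(sprintf("<track #%d> frames %d..%d, %d detection(s)\n", x$id,
              x$frame_span[1], x$frame_span[2], length(x$detections)))
  invisible(x)
}

#' Extract a centered per-cell ROI sub-sequence
#'
#' Cuts a fixed-size rectangular window around one tracked cell and
#' re-centers the cell in every retained frame by an integer translation
#' (no interpolation, so intensity values are preserved exactly for the
#' relative thresholds downstream).
#'
#' @param seq the source [frame_sequence].
#' @param track a `track` from [link_tracks].
#' @param pad_px extra margin around the track's maximal bounding box.
#' @return a `cell_trace`: `roi` ([frame_sequence] of the retained frames),
#'   `masks` and `boundaries` in ROI coordinates, `frames` (source frame
#'   indices), `offsets` (per-frame `(dy, dx)` applied), `source_track`.
#' @export
extract_roi <- function(seq, track, pad_px = 2L) {
  stopifnot(inherits(seq, "frame_sequence"), inherits(track, "track"),
            length(track$detections) >= 1L)
  bb <- t(vapply(track$detections, function(d) {
    idx <- which(d$mask, arr.ind = TRUE)
    c(diff(range(idx[, 1])) + 1L, diff(range(idx[, 2])) + 1L)
  }, numeric(2)))
  hroi <- max(bb[, 1]) + 2L * pad_px
  wroi <- max(bb[, 2]) + 2L * pad_px
  d <- dim(seq$data)
  if (hroi > d[2L] || wroi > d[3L])
    stop("ROI larger than the source image", call. = FALSE)
  cy <- (hroi + 1) / 2; cx <- (wroi + 1) / 2
  frames <- integer(0); rois <- list(); masks <- list(); bnds <- list()
  offsets <- matrix(0L, 0L, 2L)
  for (det in track$detections) {
    t <- det$frame
    # integer source position of the ROI's (1,1) pixel
    oy <- as.integer(round(det$centroid[1] - cy))
    ox <- as.integer(round(det$centroid[2] - cx))
    roi <- matrix(0, hroi, wroi)
    msk <- matrix(FALSE, hroi, wroi)
    ys <- seq_len(hroi) + oy; xs <- seq_len(wroi) + ox
    vy <- ys >= 1L & ys <= d[2L]; vx <- xs >= 1L & xs <= d[3L]
    roi[vy, vx] <- get_frame(seq, t)[ys[vy], xs[vx]]
    msk[vy, vx] <- det$mask[ys[vy], xs[vx]]
    bnd <- det$boundary
    bnd[, 1] <- bnd[, 1] - oy; bnd[, 2] <- bnd[, 2] - ox
    frames <- c(frames, t)
    rois <- c(rois, list(roi)); masks <- c(masks, list(msk))
    bnds <- c(bnds, list(bnd))
    offsets <- rbind(offsets, c(oy, ox))
  }
  structure(
    list(roi = frames_to_sequence(rois, seq), masks = masks,
         boundaries = bnds, frames = frames, offsets = offsets,
         source_track = track$id),
    class = "cell_trace")
}

#' @export
print.cell_trace <- function(x, ...) {
  d <- dim(x$roi$data)
  cat(sprintf("<cell_trace> track #%d, %d frame(s), ROI %d x %d px\n",
              x$source_track, d[1], d[2], d[3]))
  invisible(x)
}

#' Export a track as a per-frame table
#' @param track a `track`.
#' @return data.frame with frame, label, centroid_y, centroid_x, area.
#' @export
track_table <- function(track) {
  do.call(rbind, lapply(track$detections, function(d)
    data.frame(frame = d$frame, label = d$label,
               centroid_y = d$centroid[1], centroid_x = d$centroid[2],
               area = d$area_px)))
}
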