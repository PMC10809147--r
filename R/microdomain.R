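#' Label connected components of a binary image
#'
#' Breadth-first labeling with selectable 4- or 8-connectivity. Written
#' in-package because the detection contract requires both connectivities.
#'
#' @param bin logical (or 0/1) matrix.
#' @param connectivity 4 or 8.
#' @return integer matrix of component labels (0 = background).
#' @export
label_components <- function(bin, connectivity = 8L) {
  stopifnot(connectivity %in% c(4L, 8L))
  bin <- bin != 0
  h <- nrow(bin); w <- ncol(bin)
  lab <- matrix(0L, h, w)
  offs <- if (connectivity == 4L)
    cbind(c(-1L, 1L, 0L, 0L), c(0L, 0L, -1L, 1L))
  else
    cbind(c(-1L, 1L, 0L, 0L, -1L, -1L, 1L, 1L),
          c(0L, 0L, -1L, 1L, -1L, 1L, -1L, 1L))
  cur <- 0L
  for (start in which(bin)) {
    if (lab[start] != 0L) next
    cur <- cur + 1L
    queue <- start
    lab[start] <- cur
    while (length(queue)) {
      i <- queue[length(queue)]
      queue <- queue[-length(queue)]
      y <- (i - 1L) %% h + 1L
      x <- (i - 1L) %/% h + 1L
      ny <- y + offs[, 1]; nx <- x + offs[, 2]
      ok <- ny >= 1L & ny <= h & nx >= 1L & nx <= w
      ni <- (nx[ok] - 1L) * h + ny[ok]
      ni <- ni[bin[ni] & lab[ni] == 0L]
      if (length(ni)) {
        lab[ni] <- cur
        queue <- c(queue, ni)
      }
    }
  }
  lab
}

#' Detect Ca2+ microdomains in one frame
#'
#' A microdomain is a small connected set of cell pixels whose relative
#' intensity — the pixel value divided by the mean intensity over the cell
#' mask of that frame — exceeds `threshold`. Candidate pixels are grouped by
#' the chosen connectivity and filtered to `[min_size, max_size]` pixels.
#' Because the threshold is relative, detection is invariant to any global
#' positive rescaling of the frame.
#'
#' @param frame H x W intensity matrix.
#' @param mask logical cell mask, nonempty, with positive mean intensity.
#' @param threshold relative-intensity threshold (> 1), default 2.
#' @param min_size,max_size component size bounds in px (defaults 4, 200).
#' @param connectivity 4 or 8 (default 8).
#' @return list of `microdomain` objects: `frame` (NA until assigned),
#'   `pixels` (m x 2 of `(y, x)`), `centroid`, `area_px`,
#'   `mean_rel_intensity`, `max_rel_intensity`.
#' @export
detect_microdomains <- function(frame, mask, threshold = 2, min_size = 4L,
                                max_size = 200L, connectivity = 8L) {
  stopifnot(is.matrix(frame), threshold > 1)
  mask <- mask != 0
  if (!any(mask)) stop("cell mask is empty", call. = FALSE)
  m <- mean(frame[mask])
  if (m <= 0) stop("masked mean intensity is not positive", call. = FALSE)
  rel <- frame / m
  cand <- mask & rel > threshold
  if (!any(cand)) return(list())
  lab <- label_components(cand, connectivity)
  out <- list()
  for (k in seq_len(max(lab))) {
    px <- which(lab == k, arr.ind = TRUE)
    if (nrow(px) < min_size || nrow(px) > max_size) next
    vals <- rel[px]
    out[[length(out) + 1L]] <- structure(
      list(frame = NA_integer_,
           pixels = matrix(px, ncol = 2, dimnames = list(NULL, c("y", "x"))),
           centroid = c(mean(px[, 1]), mean(px[, 2])),
           area_px = nrow(px),
           mean_rel_intensity = mean(vals),
           max_rel_intensity = max(vals)),
      class = "microdomain")
  }
  out
}

#' Detect microdomains in every frame of a cell trace
#'
#' @param trace a `cell_trace` (typically shape-normalized, see
#'   [normalize_trace]).
#' @param ... passed to [detect_microdomains].
#' @return a `domain_time_series`: list with `domains` (per retained frame,
#'   a list of `microdomain`s with `frame` set to the source frame index),
#'   `frames`, `frame_interval_s`.
#' @export
detect_trace_microdomains <- function(trace, ...) {
  stopifnot(inherits(trace, "cell_trace"))
  doms <- lapply(seq_along(trace$frames), function(i) {
    ds <- detect_microdomains(get_frame(trace$roi, i), trace$masks[[i]], ...)
    lapply(ds, function(d) { d$frame <- trace$frames[i]; d })
  })
  structure(list(domains = doms, frames = trace$frames,
                 frame_interval_s = trace$roi$frame_interval_s),
            class = "domain_time_series")
}

#' Per-cell microdomain summary aligned to bead contact
#'
#' Counts domains per frame on a time axis with t = 0 at the bead contact,
#' restricted to the analysis window `pre_s` seconds before to `post_s`
#' seconds after contact. A cell is "activated" when it shows at least one
#' microdomain in at least `min_active_frames` frames from contact onward.
#'
#' @param series a `domain_time_series` from [detect_trace_microdomains].
#' @param contact a [bead_contact].
#' @param window `c(pre_s, post_s)` in seconds, default `c(1, 15)`.
#' @param min_active_frames frames with >= 1 domain needed for activation
#'   (default 1).
#' @return a `cell_summary`: `cell_id`, `t_rel_s`, `counts`, `activated`,
#'   `activation_frame` (first at/after contact with a domain, or NA),
#'   `mean_domains_per_frame` over `[0, post_s]`.
#' @export
summarize_cell <- function(series, contact, window = c(1, 15),
                           min_active_frames = 1L) {
  stopifnot(inherits(series, "domain_time_series"),
            inherits(contact, "bead_contact"))
  dt <- series$frame_interval_s
  if (!contact$contact_frame %in% series$frames)
    stop("contact frame is outside the cell trace", call. = FALSE)
  t_rel <- (series$frames - contact$contact_frame) * dt
  keep <- t_rel >= -window[1] & t_rel <= window[2]
  if (min(t_rel) > -window[1] || max(t_rel) < window[2])
    warning("analysis window extends beyond the trace; truncated",
            call. = FALSE)
  counts <- vapply(series$domains, length, 0L)[keep]
  t_rel <- t_rel[keep]
  post <- t_rel >= 0
  active_frames <- sum(counts[post] > 0)
  first_active <- if (active_frames > 0)
    series$frames[keep][post & counts > 0][1L] else NA_integer_
  structure(
    list(cell_id = contact$cell_id, t_rel_s = t_rel, counts = counts,
         activated = active_frames >= min_active_frames,
         activation_frame = first_active,
         mean_domains_per_frame = if (any(post)) mean(counts[post]) else 0),
    class = "cell_summary")
}

#' Aggregate per-cell summaries over a cell group
#'
#' @param summaries list of `cell_summary` objects (>= 1).
#' @return a `group_summary`: `n_cells`, `activated_fraction`, and
#'   `timepoints`, a data.frame with `t_rel_s`, `mean`, `sem`, `n` (SEM is
#'   reported as 0 with `sem_defined = FALSE` when n = 1).
#' @export
aggregate_group <- function(summaries) {
  stopifnot(length(summaries) >= 1L)
  act <- vapply(summaries, function(s) s$activated, TRUE)
  tp <- sort(unique(round(unlist(lapply(summaries, function(s) s$t_rel_s)),
                          9)))
  rows <- lapply(tp, function(t0) {
    vals <- unlist(lapply(summaries, function(s) {
      i <- which(abs(s$t_rel_s - t0) < 1e-9)
      if (length(i)) s$counts[i] else NULL
    }))
    n <- length(vals)
    sem <- if (n > 1) stats::sd(vals) / sqrt(n) else 0
    data.frame(t_rel_s = t0, mean = mean(vals), sem = sem, n = n,
               sem_defined = n > 1)
  })
  structure(
    list(n_cells = length(summaries),
         activated_fraction = mean(act),
         timepoints = do.call(rbind, rows)),
    class = "group_summary")
}

#' @export
print.group_summary <- function(x, ...) {
  cat(sprintf(
    "<group_summary> %d cell(s), activated fraction %.3f, %d timepoint(s)\n",
    x$n_cells, x$activated_fraction, nrow(x$timepoints)))
  invisible(x)
}

#' Export detected domains of one cell as a long table
#'
#' @param series a `domain_time_series`.
#' @param contact optional [bead_contact] for the relative time column.
#' @return data.frame: frame, t_rel_s, domain_id, centroid_y, centroid_x,
#'   area_px, mean_rel, max_rel.
#' @export
domain_table <- function(series, contact = NULL) {
  dt <- series$frame_interval_s
  c0 <- if (is.null(contact)) series$frames[1L] else contact$contact_frame
  rows <- list()
  id <- 0L
  for (i in seq_along(series$frames)) {
    for (d in series$domains[[i]]) {
      id <- id + 1L
      rows[[id]] <- data.frame(
        frame = d$frame, t_rel_s = (d$frame - c0) * dt, domain_id = id,
        centroid_y = d$centroid[1], centroid_x = d$centroid[2],
        area_px = d$area_px, mean_rel = d$mean_rel_intensity,
        max_rel = d$max_rel_intensity)
    }
  }
  if (!length(rows))
    return(data.frame(frame = integer(0), t_rel_s = numeric(0),
                      domain_id = integer(0), centroid_y = numeric(0),
                      centroid_x = numeric(0), area_px = integer(0),
                      mean_rel = numeric(0), max_rel = numeric(0)))
  do.call(rbind, rows)
}
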