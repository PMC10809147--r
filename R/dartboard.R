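#' Bead contact annotation
#'
#' The stimulation event for one cell: the frame at which an antibody-coated
#' bead touches the membrane, and where on the cell perimeter it touches,
#' encoded as an hour hand on a clock face overlaid on the image
#' (12 = up, 3 = right, 6 = down, 9 = left; fractional hours allowed).
#'
#' @param cell_id identifier of the cell.
#' @param contact_frame frame index of first contact (1-based).
#' @param clock_position real in (0, 12].
#' @return a `bead_contact`.
#' @export
bead_contact <- function(cell_id, contact_frame, clock_position) {
  if (!is.numeric(clock_position) || clock_position <= 0 ||
      clock_position > 12)
    stop("clock_position must lie in (0, 12]", call. = FALSE)
  structure(list(cell_id = cell_id,
                 contact_frame = as.integer(contact_frame),
                 clock_position = as.numeric(clock_position)),
            class = "bead_contact")
}

#' Read bead contacts from a sidecar CSV
#'
#' Expected columns: `cell_id, contact_frame, clock_position`.
#'
#' @param path CSV path.
#' @return named list of [bead_contact]s keyed by cell_id.
#' @export
read_bead_contacts <- function(path) {
  if (!file.exists(path))
    stop(sprintf("bead-contact sidecar not found: %s", path), call. = FALSE)
  df <- utils::read.csv(path)
  need <- c("cell_id", "contact_frame", "clock_position")
  if (!all(need %in% names(df)))
    stop("sidecar must have columns cell_id, contact_frame, clock_position",
         call. = FALSE)
  out <- lapply(seq_len(nrow(df)), function(i)
    bead_contact(df$cell_id[i], df$contact_frame[i], df$clock_position[i]))
  names(out) <- as.character(df$cell_id)
  out
}

#' Convert a clock position to an image-plane angle
#'
#' `angle = pi/2 - clock * pi/6`, wrapped to \[0, 2pi): 12 points up
#' (pi/2), 3 right (0), 6 down (3pi/2), 9 left (pi). Angles are measured
#' counterclockwise from +x with "up" = decreasing row index, matching
#' [outline_to_polar].
#'
#' @param clock_position real in (0, 12].
#' @return angle in radians in \[0, 2pi).
#' @export
clock_to_angle <- function(clock_position) {
  if (any(clock_position <= 0) || any(clock_position > 12))
    stop("clock_position must lie in (0, 12]", call. = FALSE)
  (pi / 2 - clock_position * pi / 6) %% (2 * pi)
}

#' Equal-area dartboard geometry
#'
#' A central bullseye disk plus `n_rings` annuli, each annulus holding
#' `n_segments` angular sectors. The annulus boundaries
#' `r_k = R * sqrt(b^2 + k (1 - b^2) / n_rings)` make all annuli equal in
#' area, so ring widths shrink outward and every non-bullseye segment covers
#' the same cell area.
#'
#' @param n_segments angular divisions per ring (default 12).
#' @param n_rings annuli outside the bullseye (default 5).
#' @param bullseye_frac bullseye radius / board radius, in (0, 1)
#'   (default 0.2).
#' @param radius board radius R (default 1; use the template radius in px to
#'   get areas in px^2).
#' @return a `dartboard_geometry`: `ring_radii` (length n_rings, ending at
#'   R), `bullseye_area`, `segment_area` (identical for all non-bullseye
#'   segments), plus the parameters.
#' @export
dartboard_geometry <- function(n_segments = 12L, n_rings = 5L,
                               bullseye_frac = 0.2, radius = 1) {
  stopifnot(n_segments >= 1L, n_rings >= 1L,
            bullseye_frac > 0, bullseye_frac < 1, radius > 0)
  b <- bullseye_frac
  k <- seq_len(n_rings)
  ring_radii <- radius * sqrt(b^2 + k * (1 - b^2) / n_rings)
  ring_area <- pi * radius^2 * (1 - b^2) / n_rings
  structure(
    list(n_segments = as.integer(n_segments), n_rings = as.integer(n_rings),
         bullseye_frac = b, radius = radius, ring_radii = ring_radii,
         bullseye_area = pi * (b * radius)^2,
         segment_area = ring_area / n_segments),
    class = "dartboard_geometry")
}

#' @export
print.dartboard_geometry <- function(x, ...) {
  cat(sprintf(
    "<dartboard_geometry> bullseye + %d ring(s) x %d segment(s), R = %g\n",
    x$n_rings, x$n_segments, x$radius))
  invisible(x)
}

#' Align a cell's microdomains to its bead contact
#'
#' Each domain centroid is expressed in polar coordinates about the board
#' center, rotated so every cell's contact direction coincides with
#' `reference_angle`, and time-shifted so t = 0 is the contact frame.
#'
#' @param series a `domain_time_series` in shape-normalized coordinates.
#' @param contact the cell's [bead_contact].
#' @param board_center `(y, x)` center of the dartboard (the normalized
#'   cell's centroid).
#' @param template_radius template circle radius in px.
#' @param reference_angle common contact direction after alignment
#'   (default 0, i.e. clock 3 / east).
#' @return data.frame of aligned events: `cell_id, t_rel_s, r_frac,
#'   theta_aligned` (r_frac clipped to \[0, 1\]).
#' @export
align_domains <- function(series, contact, board_center, template_radius,
                          reference_angle = 0) {
  stopifnot(inherits(series, "domain_time_series"),
            inherits(contact, "bead_contact"), template_radius > 0)
  dt <- series$frame_interval_s
  contact_angle <- clock_to_angle(contact$clock_position)
  rows <- list()
  for (i in seq_along(series$frames)) {
    for (d in series$domains[[i]]) {
      dx <- d$centroid[2] - board_center[2]
      dy_up <- board_center[1] - d$centroid[1]
      r <- sqrt(dx^2 + dy_up^2)
      th <- atan2(dy_up, dx)
      rows[[length(rows) + 1L]] <- data.frame(
        cell_id = contact$cell_id,
        t_rel_s = (d$frame - contact$contact_frame) * dt,
        r_frac = min(r / template_radius, 1),
        theta_aligned = (th - contact_angle + reference_angle) %% (2 * pi))
    }
  }
  if (!length(rows))
    return(data.frame(cell_id = character(0), t_rel_s = numeric(0),
                      r_frac = numeric(0), theta_aligned = numeric(0)))
  do.call(rbind, rows)
}

#' Assign an aligned event to a dartboard area
#'
#' Bullseye when `r_frac < bullseye_frac`; otherwise ring k with
#' `r_{k-1} <= r_frac * R < r_k`. Segment 1 is centered on the contact
#' direction (`reference_angle`), i.e. segment boundaries are offset by half
#' a segment width. Vectorized over events.
#'
#' @param r_frac radial position(s) in \[0, 1\].
#' @param theta_aligned aligned angle(s) in radians.
#' @param geom a [dartboard_geometry].
#' @param reference_angle as in [align_domains] (default 0).
#' @return data.frame `ring` (0 = bullseye, 1..n_rings outward) and
#'   `segment` (1..n_segments; 1 for the bullseye).
#' @export
assign_segment <- function(r_frac, theta_aligned, geom,
                           reference_angle = 0) {
  stopifnot(inherits(geom, "dartboard_geometry"))
  if (any(r_frac < 0)) stop("r_frac must be >= 0", call. = FALSE)
  if (any(r_frac > 1)) {
    warning("r_frac > 1 clipped to the outermost ring", call. = FALSE)
    r_frac <- pmin(r_frac, 1)
  }
  r <- r_frac * geom$radius
  bull <- r < geom$bullseye_frac * geom$radius
  ring <- findInterval(r, c(geom$bullseye_frac * geom$radius,
                            geom$ring_radii[-geom$n_rings]))
  ring[bull] <- 0L
  ring[!bull] <- pmax(ring[!bull], 1L)
  ring <- pmin(ring, geom$n_rings)
  halfw <- pi / geom$n_segments
  seg <- 1L + floor(((theta_aligned - reference_angle + halfw) %%
                       (2 * pi)) / (2 * pi / geom$n_segments))
  seg <- pmin(as.integer(seg), geom$n_segments)
  seg[bull] <- 1L
  data.frame(ring = as.integer(ring), segment = seg)
}

#' Accumulate aligned events into dartboard densities
#'
#' Pools events from all cells into per-(time bin, ring, segment) counts and
#' converts them to densities: `count / (segment_area * bin_seconds *
#' n_cells)`, i.e. microdomains per unit area per second per cell. The
#' per-area normalization compensates for the larger bullseye.
#'
#' @param events data.frame of aligned events ([align_domains] output,
#'   possibly row-bound over cells).
#' @param geom a [dartboard_geometry].
#' @param time_bins list of `c(start_s, end_s)` half-open bins, or a 2-column
#'   matrix; must be non-overlapping. Default `0-5`, `5-10`, `10-15` s.
#' @param n_cells number of cells pooled (>= 1).
#' @param reference_angle as in [align_domains].
#' @return a `dartboard_accumulator`: `counts` and `densities`, arrays of
#'   dim `(n_bins, n_rings + 1, n_segments)` (ring index 1 = bullseye, whose
#'   count sits in segment 1), plus `geom`, `time_bins`, `n_cells`.
#' @export
dartboard_accumulate <- function(events, geom,
                                 time_bins = list(c(0, 5), c(5, 10),
                                                  c(10, 15)),
                                 n_cells, reference_angle = 0) {
  stopifnot(inherits(geom, "dartboard_geometry"))
  if (missing(n_cells) || n_cells < 1L)
    stop("`n_cells` must be >= 1", call. = FALSE)
  if (is.matrix(time_bins))
    time_bins <- lapply(seq_len(nrow(time_bins)),
                        function(i) time_bins[i, ])
  bins <- do.call(rbind, time_bins)
  if (any(bins[, 2] <= bins[, 1]))
    stop("each time bin needs end > start", call. = FALSE)
  ord <- order(bins[, 1])
  if (any(bins[ord, 1][-1] < bins[ord, 2][-nrow(bins)]))
    stop("time bins must not overlap", call. = FALSE)
  nb <- nrow(bins)
  counts <- array(0L, dim = c(nb, geom$n_rings + 1L, geom$n_segments))
  if (nrow(events)) {
    asg <- assign_segment(events$r_frac, events$theta_aligned, geom,
                          reference_angle)
    for (e in seq_len(nrow(events))) {
      b <- which(events$t_rel_s[e] >= bins[, 1] &
                   events$t_rel_s[e] < bins[, 2])
      if (length(b) != 1L) next  # outside all bins
      counts[b, asg$ring[e] + 1L, asg$segment[e]] <-
        counts[b, asg$ring[e] + 1L, asg$segment[e]] + 1L
    }
  }
  dens <- array(0, dim = dim(counts))
  dur <- bins[, 2] - bins[, 1]
  for (b in seq_len(nb)) {
    dens[b, 1L, ] <- counts[b, 1L, ] / (geom$bullseye_area * dur[b] * n_cells)
    dens[b, -1L, ] <- counts[b, -1L, ] /
      (geom$segment_area * dur[b] * n_cells)
  }
  structure(list(counts = counts, densities = dens, geom = geom,
                 time_bins = bins, n_cells = as.integer(n_cells),
                 reference_angle = reference_angle),
            class = "dartboard_accumulator")
}

#' @export
print.dartboard_accumulator <- function(x, ...) {
  cat(sprintf(
    "<dartboard_accumulator> %d bin(s), %d cell(s), %d event(s) assigned\n",
    nrow(x$time_bins), x$n_cells, sum(x$counts)))
  invisible(x)
}

#' Long-format export of a dartboard accumulator
#' @param acc a `dartboard_accumulator`.
#' @return data.frame: time_bin_start, time_bin_end, ring, segment, count,
#'   area, density, n_cells.
#' @export
dartboard_table <- function(acc) {
  g <- acc$geom
  rows <- list()
  for (b in seq_len(nrow(acc$time_bins)))
    for (r in 0:g$n_rings)
      for (s in seq_len(if (r == 0) 1L else g$n_segments))
        rows[[length(rows) + 1L]] <- data.frame(
          time_bin_start = acc$time_bins[b, 1],
          time_bin_end = acc$time_bins[b, 2],
          ring = r, segment = s,
          count = acc$counts[b, r + 1L, s],
          area = if (r == 0) g$bullseye_area else g$segment_area,
          density = acc$densities[b, r + 1L, s],
          n_cells = acc$n_cells)
  do.call(rbind, rows)
}

#' Moving-average smoothing of fine-binned dartboard densities
#'
#' Centered moving average over time for every (ring, segment) cell of an
#' accumulator built on uniform fine bins. Edge bins use the partial window
#' that fits.
#'
#' @param acc a `dartboard_accumulator` over uniform bins.
#' @param window_s averaging window in seconds (>= one bin width).
#' @return array like `acc$densities`, smoothed along the first axis.
#' @export
moving_average_densities <- function(acc, window_s) {
  stopifnot(inherits(acc, "dartboard_accumulator"))
  widths <- acc$time_bins[, 2] - acc$time_bins[, 1]
  if (max(widths) - min(widths) > 1e-9)
    stop("moving average requires uniform time bins", call. = FALSE)
  bw <- widths[1]
  if (window_s < bw)
    stop("window must be at least one bin wide", call. = FALSE)
  wb <- max(1L, round(window_s / bw))
  if (wb %% 2L == 0L) wb <- wb + 1L  # centered window
  half <- (wb - 1L) %/% 2L
  nb <- nrow(acc$time_bins)
  out <- array(0, dim = dim(acc$densities))
  for (b in seq_len(nb)) {
    lo <- max(1L, b - half); hi <- min(nb, b + half)
    out[b, , ] <- apply(acc$densities[lo:hi, , , drop = FALSE],
                        c(2, 3), mean)
  }
  out
}

#' Render a dartboard density panel
#'
#' Draws one time bin of an accumulator as a polar heatmap (base graphics):
#' wedge color encodes density, with the contact direction marked. The
#' mapping from density to color is linear over `zlim`, so the plot is
#' deterministic given its inputs.
#'
#' @param acc a `dartboard_accumulator`.
#' @param bin index of the time bin to draw (default 1).
#' @param palette color ramp function (n -> colors); default gray to red.
#' @param zlim density range mapped onto the palette; defaults to
#'   `c(0, max(density))`.
#' @param main plot title.
#' @return invisibly, the matrix of colors drawn (rings x segments).
#' @export
render_dartboard <- function(acc, bin = 1L, palette = NULL, zlim = NULL,
                             main = NULL) {
  stopifnot(inherits(acc, "dartboard_accumulator"),
            bin >= 1L, bin <= nrow(acc$time_bins))
  g <- acc$geom
  if (is.null(palette))
    palette <- grDevices::colorRampPalette(c("grey92", "orange", "red3"))
  cols256 <- palette(256L)
  dens <- acc$densities[bin, , ]
  if (is.null(zlim)) zlim <- c(0, max(dens, 1e-12))
  to_col <- function(v) {
    i <- 1L + as.integer(round(255 *
      pmin(pmax((v - zlim[1]) / (zlim[2] - zlim[1]), 0), 1)))
    cols256[i]
  }
  graphics::plot(NA, xlim = c(-1.25, 1.25), ylim = c(-1.25, 1.25),
                 asp = 1, axes = FALSE, xlab = "", ylab = "",
                 main = if (is.null(main))
                   sprintf("%g-%g s", acc$time_bins[bin, 1],
                           acc$time_bins[bin, 2]) else main)
  radii <- c(g$bullseye_frac, g$ring_radii / g$radius)
  halfw <- pi / g$n_segments
  colmat <- matrix("", g$n_rings + 1L, g$n_segments)
  phi <- seq(0, 2 * pi, length.out = 120L)
  # bullseye
  colmat[1L, ] <- to_col(dens[1L, 1L])
  graphics::polygon(radii[1] * cos(phi), radii[1] * sin(phi),
                    col = colmat[1L, 1L], border = "white")
  for (r in seq_len(g$n_rings)) {
    for (s in seq_len(g$n_segments)) {
      a0 <- acc$reference_angle - halfw + (s - 1L) * 2 * halfw
      a1 <- a0 + 2 * halfw
      aa <- seq(a0, a1, length.out = 24L)
      xs <- c(radii[r] * cos(aa), radii[r + 1L] * cos(rev(aa)))
      ys <- c(radii[r] * sin(aa), radii[r + 1L] * sin(rev(aa)))
      colmat[r + 1L, s] <- to_col(dens[r + 1L, s])
      graphics::polygon(xs, ys, col = colmat[r + 1L, s], border = "white")
    }
  }
  graphics::arrows(1.02 * cos(acc$reference_angle),
                   1.02 * sin(acc$reference_angle),
                   1.2 * cos(acc$reference_angle),
                   1.2 * sin(acc$reference_angle),
                   length = 0.08, lwd = 2)
  graphics::text(1.25 * cos(acc$reference_angle),
                 1.25 * sin(acc$reference_angle), "bead", xpd = NA)
  invisible(colmat)
}
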