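#' Specification for a synthetic ratiometric video
#'
#' Describes a bead-stimulation experiment to simulate: star-convex cells
#' (radial Fourier perturbations of a circle) that drift and deform slowly,
#' two spectrally complementary channels whose ratio rises at Ca2+ events,
#' localized transient bright microdomains placed preferentially near the
#' bead contact, monotone biexponential bleaching of the second channel,
#' and Gaussian read noise with optional Poisson shot noise. A fixed seed
#' makes the output bit-reproducible.
#'
#' @param n_cells number of cells in the field of view.
#' @param image_size `c(H, W)` in px.
#' @param n_frames frames to render.
#' @param frame_interval_s seconds per frame.
#' @param cell_radius_px mean cell radius.
#' @param radius_jitter_px half-range of per-cell uniform radius jitter.
#' @param shape_harmonics list of `c(order, amplitude)` radial Fourier
#'   perturbations of the boundary (relative amplitude); `NULL` for perfect
#'   disks.
#' @param deform_rate_rad_per_frame phase drift of the harmonics, producing
#'   slow deformation.
#' @param drift_px_per_frame `c(dy, dx)` translation per frame.
#' @param contact_frame bead-contact frame for every cell.
#' @param contact_clock clock positions (length 1 or n_cells); `NULL` draws
#'   them uniformly from 1..12.
#' @param rate_near,rate_far microdomain event rates (events/s) near the
#'   contact vs elsewhere; "near" means within `near_clock_halfwidth` clock
#'   hours of the contact and `r_frac >= near_rfrac_min`.
#' @param near_clock_halfwidth,near_rfrac_min the near-contact region.
#' @param spot_sigma_px Gaussian spot sigma of an event.
#' @param amplitude_rel event peak amplitude as a multiple of the cell's
#'   mean ch1 intensity.
#' @param duration_frames frames an event stays bright.
#' @param base_ch1,base_ch2,background intra-cell and background intensity
#'   levels.
#' @param bleach `NULL` or list `a, b1, tau1, b2, tau2`: the fraction of the
#'   initial ch2 intensity retained at time t,
#'   `f(t) = a + b1 exp(-t/tau1) + b2 exp(-t/tau2)`.
#' @param noise_sigma Gaussian read-noise sd (intensity units).
#' @param poisson also apply Poisson shot noise.
#' @param channel_shift_px known `(dy, dx)` misalignment applied to ch2
#'   (may be fractional), for registration-recovery experiments.
#' @param scripted_events `NULL` or data.frame with columns
#'   `cell, frame, clock, r_frac`: events placed deterministically in
#'   addition to the random ones.
#' @param seed integer seed fixing all randomness.
#' @return a `synthetic_spec` list.
#' @export
synthetic_spec <- function(n_cells = 1L, image_size = c(64L, 64L),
                           n_frames = 36L, frame_interval_s = 0.5,
                           cell_radius_px = 18, radius_jitter_px = 2,
                           shape_harmonics = list(c(3, 0.05)),
                           deform_rate_rad_per_frame = 0.02,
                           drift_px_per_frame = c(0, 0),
                           contact_frame = 4L, contact_clock = NULL,
                           rate_near = 1.0, rate_far = 0.1,
                           near_clock_halfwidth = 1, near_rfrac_min = 0.6,
                           spot_sigma_px = 1.5, amplitude_rel = 3,
                           duration_frames = 2L,
                           base_ch1 = 100, base_ch2 = 120, background = 8,
                           bleach = list(a = 0.35, b1 = 0.25, tau1 = 3,
                                         b2 = 0.40, tau2 = 12),
                           noise_sigma = 5, poisson = FALSE,
                           channel_shift_px = c(0, 0),
                           scripted_events = NULL, seed = 1L) {
  stopifnot(n_cells >= 1L, n_frames >= 1L, frame_interval_s > 0,
            cell_radius_px > 0, rate_near >= 0, rate_far >= 0,
            amplitude_rel >= 0, noise_sigma >= 0)
  if (!is.null(shape_harmonics))
    stopifnot(all(vapply(shape_harmonics, function(h) h[2] >= 0, TRUE)))
  structure(as.list(environment()), class = "synthetic_spec")
}

bleach_fraction <- function(bleach, t) {
  if (is.null(bleach)) return(rep(1, length(t)))
  f <- bleach$a + bleach$b1 * exp(-t / bleach$tau1) +
    bleach$b2 * exp(-t / bleach$tau2)
  f / f[1L]
}

# radius of cell `i` at angle theta and frame t (vectorized over theta)
cell_radius_fun <- function(radius, harmonics, phases, deform_rate) {
  function(theta, t = 1L) {
    r <- rep(radius, length(theta))
    if (!is.null(harmonics))
      for (j in seq_along(harmonics)) {
        h <- harmonics[[j]]
        r <- r + radius * h[2] *
          cos(h[1] * theta + phases[j] + deform_rate * (t - 1L))
      }
    r
  }
}

#' Place an event at a scripted polar location inside a cell
#'
#' Converts a `(clock_position, r_frac)` location relative to a cell's
#' centroid into Cartesian pixel coordinates on the cell's (possibly
#' non-circular) outline. If a mask is supplied and the point falls outside
#' it (concave outline), the radius is shrunk stepwise with a warning.
#'
#' @param center `(y, x)` cell centroid.
#' @param radius_at function `theta -> outline radius` (a constant radius
#'   may be given as a single number).
#' @param clock_position clock position of the event (0, 12].
#' @param r_frac relative radial position in \[0, 1\].
#' @param frame frame index carried through.
#' @param mask optional logical matrix to verify membership.
#' @return list `y, x, frame`.
#' @export
scripted_event_placement <- function(center, radius_at, clock_position,
                                     r_frac, frame, mask = NULL) {
  stopifnot(r_frac >= 0, r_frac <= 1)
  if (is.numeric(radius_at)) {
    r0 <- radius_at
    radius_at <- function(theta) rep(r0, length(theta))
  }
  th <- clock_to_angle(clock_position)
  q <- r_frac
  repeat {
    r <- q * radius_at(th)
    y <- center[1] - r * sin(th)
    x <- center[2] + r * cos(th)
    if (is.null(mask)) break
    yi <- max(1L, min(nrow(mask), round(y)))
    xi <- max(1L, min(ncol(mask), round(x)))
    if (mask[yi, xi]) break
    if (q < 0.05) { y <- center[1]; x <- center[2]; break }
    warning("scripted event outside mask; reducing r_frac", call. = FALSE)
    q <- q * 0.8
  }
  list(y = y, x = x, frame = as.integer(frame))
}

#' Generate a synthetic ratiometric dataset with ground truth
#'
#' Renders the two indicator channels described by a [synthetic_spec],
#' returning the noisy [channel_pair], the full ground truth (per-frame
#' label masks, the emitted events, cell geometry, the clean per-frame
#' channel means) and a bead-contact sidecar table. Optionally writes the
#' TIFF + CSV files the pipeline consumes.
#'
#' @param spec a [synthetic_spec].
#' @param dir optional output directory; when given, writes `ch1.tif`,
#'   `ch2.tif`, `contacts.csv`, `events.csv` and `spec.json` there.
#' @return list with `pair` ([channel_pair]), `truth` (list: `events`
#'   data.frame, `labels` per-frame integer masks, `cells` data.frame,
#'   `bleach_curve`, `clean_means` per-frame true in-cell channel means),
#'   `contacts` (list of [bead_contact]), `sidecar` (data.frame).
#' @export
generate_dataset <- function(spec, dir = NULL) {
  stopifnot(inherits(spec, "synthetic_spec"))
  set.seed(spec$seed)
  H <- spec$image_size[1]; W <- spec$image_size[2]
  nT <- spec$n_frames; nC <- spec$n_cells
  # cell layout on a grid
  ngx <- ceiling(sqrt(nC)); ngy <- ceiling(nC / ngx)
  amp_sum <- if (is.null(spec$shape_harmonics)) 0 else
    sum(vapply(spec$shape_harmonics, function(h) h[2], 0))
  radii <- spec$cell_radius_px +
    stats::runif(nC, -spec$radius_jitter_px, spec$radius_jitter_px)
  rmax <- max(radii) * (1 + amp_sum)
  drift_tot <- abs(spec$drift_px_per_frame) * (nT - 1L)
  need_y <- 2 * (rmax + 2) + drift_tot[1]
  need_x <- 2 * (rmax + 2) + drift_tot[2]
  if (ngy * need_y > H || ngx * need_x > W)
    stop("cells would overlap or leave the field; enlarge image_size or ",
         "reduce n_cells/cell_radius_px", call. = FALSE)
  centers0 <- cbind(
    y = (rep(seq_len(ngy), each = ngx)[seq_len(nC)] - 0.5) * H / ngy,
    x = (rep(seq_len(ngx), times = ngy)[seq_len(nC)] - 0.5) * W / ngx)
  clocks <- if (is.null(spec$contact_clock)) sample(1:12, nC, replace = TRUE)
            else rep(spec$contact_clock, length.out = nC)
  phases <- lapply(seq_len(nC), function(i)
    stats::runif(length(spec$shape_harmonics), 0, 2 * pi))
  rfuns <- lapply(seq_len(nC), function(i)
    cell_radius_fun(radii[i], spec$shape_harmonics, phases[[i]],
                    spec$deform_rate_rad_per_frame))

  # ---- draw events ---------------------------------------------------
  dt <- spec$frame_interval_s
  wrap_clock <- function(cl) ((cl - 1e-12) %% 12) + 1e-12
  clock_dist <- function(a, b) { d <- abs(a - b) %% 12; pmin(d, 12 - d) }
  events <- list()
  for (i in seq_len(nC)) {
    for (t in spec$contact_frame:nT) {
      n_near <- stats::rpois(1L, spec$rate_near * dt)
      n_far <- stats::rpois(1L, spec$rate_far * dt)
      if (n_near > 0) for (k in seq_len(n_near)) {
        cl <- wrap_clock(clocks[i] + stats::runif(1, -spec$near_clock_halfwidth,
                                                  spec$near_clock_halfwidth))
        q <- stats::runif(1, spec$near_rfrac_min, 0.95)
        events[[length(events) + 1L]] <-
          data.frame(cell = i, frame = t, clock = cl, r_frac = q,
                     is_near_contact = TRUE, scripted = FALSE)
      }
      if (n_far > 0) for (k in seq_len(n_far)) {
        for (try in 1:20) {
          cl <- wrap_clock(stats::runif(1, 0, 12))
          q <- sqrt(stats::runif(1)) * 0.95
          near <- clock_dist(cl, clocks[i]) <= spec$near_clock_halfwidth &&
            q >= spec$near_rfrac_min
          if (!near) break
        }
        events[[length(events) + 1L]] <-
          data.frame(cell = i, frame = t, clock = cl, r_frac = q,
                     is_near_contact = FALSE, scripted = FALSE)
      }
    }
  }
  if (!is.null(spec$scripted_events))
    for (e in seq_len(nrow(spec$scripted_events))) {
      se <- spec$scripted_events[e, ]
      events[[length(events) + 1L]] <-
        data.frame(cell = se$cell, frame = se$frame, clock = se$clock,
                   r_frac = se$r_frac,
                   is_near_contact =
                     clock_dist(se$clock, clocks[se$cell]) <=
                       spec$near_clock_halfwidth &&
                     se$r_frac >= spec$near_rfrac_min,
                   scripted = TRUE)
    }
  events <- if (length(events)) do.call(rbind, events) else
    data.frame(cell = integer(0), frame = integer(0), clock = numeric(0),
               r_frac = numeric(0), is_near_contact = logical(0),
               scripted = logical(0))

  # ---- render frames -------------------------------------------------
  bl <- bleach_fraction(spec$bleach, (seq_len(nT) - 1L) * dt)
  ch1 <- array(spec$background, dim = c(nT, H, W))
  ch2 <- array(spec$background, dim = c(nT, H, W))
  labels <- vector("list", nT)
  gy <- matrix(seq_len(H), H, W); gx <- matrix(seq_len(W), H, W, byrow = TRUE)
  ev_pos <- matrix(NA_real_, nrow(events), 2)
  clean_means <- matrix(0, nT, 2)
  for (t in seq_len(nT)) {
    lab <- matrix(0L, H, W)
    f1 <- matrix(spec$background, H, W)
    f2 <- matrix(spec$background, H, W)
    for (i in seq_len(nC)) {
      ctr <- centers0[i, ] + spec$drift_px_per_frame * (t - 1L)
      dx <- gx - ctr[2]; dy_up <- ctr[1] - gy
      rr <- sqrt(dx^2 + dy_up^2)
      th <- atan2(dy_up, dx) %% (2 * pi)
      inside <- rr <= rfuns[[i]](th, t)
      lab[inside] <- i
      f1[inside] <- spec$base_ch1
      f2[inside] <- spec$base_ch2 * bl[t]
    }
    # paint active events
    act <- which(events$frame <= t &
                   events$frame + spec$duration_frames - 1L >= t)
    for (e in act) {
      i <- events$cell[e]
      ctr <- centers0[i, ] + spec$drift_px_per_frame * (events$frame[e] - 1L)
      pos <- scripted_event_placement(
        ctr, function(th2) rfuns[[i]](th2, events$frame[e]),
        events$clock[e], events$r_frac[e], events$frame[e])
      if (t == events$frame[e]) ev_pos[e, ] <- c(pos$y, pos$x)
      spot <- spec$amplitude_rel * spec$base_ch1 *
        exp(-((gy - pos$y)^2 + (gx - pos$x)^2) / (2 * spec$spot_sigma_px^2))
      f1 <- f1 + spot
      f2 <- pmax(f2 - 0.4 * spot * spec$base_ch2 / spec$base_ch1, 1)
    }
    labels[[t]] <- lab
    clean_means[t, ] <- c(mean(f1[lab > 0]), mean(f2[lab > 0]))
    ch1[t, , ] <- f1
    ch2[t, , ] <- f2
  }
  # known channel misalignment of ch2
  if (any(spec$channel_shift_px != 0)) {
    tf <- affine_transform2d(diag(2), spec$channel_shift_px)
    for (t in seq_len(nT))
      ch2[t, , ] <- warp_frame(matrix(ch2[t, , ], H, W), tf, "linear")
  }
  # noise
  if (spec$poisson) {
    ch1[] <- stats::rpois(length(ch1), pmax(ch1, 0))
    ch2[] <- stats::rpois(length(ch2), pmax(ch2, 0))
  }
  if (spec$noise_sigma > 0) {
    ch1 <- ch1 + stats::rnorm(length(ch1), 0, spec$noise_sigma)
    ch2 <- ch2 + stats::rnorm(length(ch2), 0, spec$noise_sigma)
  }
  ch1[ch1 < 0] <- 0; ch2[ch2 < 0] <- 0

  events$y <- ev_pos[, 1]; events$x <- ev_pos[, 2]
  pair <- channel_pair(
    frame_sequence(ch1, frame_interval_s = dt),
    frame_sequence(ch2, frame_interval_s = dt))
  sidecar <- data.frame(cell_id = seq_len(nC),
                        contact_frame = spec$contact_frame,
                        clock_position = clocks,
                        centroid_y = centers0[, 1], centroid_x = centers0[, 2])
  contacts <- lapply(seq_len(nC), function(i)
    bead_contact(i, spec$contact_frame, clocks[i]))
  names(contacts) <- as.character(seq_len(nC))
  truth <- list(events = events, labels = labels,
                cells = data.frame(cell_id = seq_len(nC),
                                   center_y = centers0[, 1],
                                   center_x = centers0[, 2],
                                   radius_px = radii,
                                   contact_clock = clocks),
                bleach_curve = bl, clean_means = clean_means)
  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    write_tiff_sequence(pair$ch1, file.path(dir, "ch1.tif"), "float32")
    write_tiff_sequence(pair$ch2, file.path(dir, "ch2.tif"), "float32")
    utils::write.csv(sidecar, file.path(dir, "contacts.csv"),
                     row.names = FALSE)
    utils::write.csv(events, file.path(dir, "events.csv"), row.names = FALSE)
    jsonlite::write_json(spec[setdiff(names(spec), "scripted_events")],
                         file.path(dir, "spec.json"), auto_unbox = TRUE,
                         force = TRUE)
  }
  list(pair = pair, truth = truth, contacts = contacts, sidecar = sidecar)
}
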