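#' Default pipeline configuration
#'
#' All recognized configuration keys with their defaults. `run_pipeline`
#' rejects unknown keys so typos fail loudly, and writes the fully resolved
#' configuration next to its outputs for provenance.
#'
#' @return named list of defaults.
#' @export
default_config <- function() {
  list(
    # inputs
    input_ch1 = NULL, input_ch2 = NULL, input_raw = NULL,
    dual_view_layout = "left-right",
    contacts = NULL, out_dir = "microdart_out", group_label = "group",
    pixel_size_um = 1, frame_interval_s = 1,
    # postprocessing
    register_mode = "first_frame",      # first_frame | per_frame | none
    background_mode = "percentile",     # percentile | roi | constant | none
    background_percentile = 1, background_value = 0, background_roi = NULL,
    ratio_clip_lo = NULL, ratio_clip_hi = NULL,
    bleach_mode = "additive",           # none | additive | multiplicative | biexp
    bleach_channel = "ch2",
    # deconvolution
    deconvolve = "none",                # none | lucy_richardson
    psf = "gaussian:1.5", lr_iterations = 10,
    # detection & tracking
    seg_backend = "threshold", min_area_px = 30, max_disp_px = 10,
    min_frames = NULL, max_gap = 2, roi_pad_px = 3,
    # shape normalization
    shape_norm = TRUE, scale_factor_c = 1,
    # microdomain detection
    threshold = 2, min_size = 4, max_size = 200, connectivity = 8,
    window_pre_s = 1, window_post_s = 15, min_active_frames = 1,
    # dartboard
    n_segments = 12, n_rings = 5, bullseye_frac = 0.2,
    time_bins = list(c(0, 5), c(5, 10), c(10, 15)),
    reference_angle = 0)
}

#' Load and resolve a pipeline configuration
#'
#' @param config path to a YAML file, or a named list of overrides.
#' @return resolved config list (defaults filled in); unknown keys error.
#' @export
load_config <- function(config = list()) {
  if (is.character(config)) {
    if (!file.exists(config))
      stop(sprintf("config file not found: %s", config), call. = FALSE)
    config <- yaml::read_yaml(config)
    if (is.null(config)) config <- list()
  }
  base <- default_config()
  unknown <- setdiff(names(config), names(base))
  if (length(unknown))
    stop(sprintf("unknown config key(s): %s",
                 paste(unknown, collapse = ", ")), call. = FALSE)
  base[names(config)] <- config
  base
}

resolve_psf <- function(cfg) {
  if (startsWith(cfg$psf, "gaussian:"))
    gaussian_psf(as.numeric(sub("gaussian:", "", cfg$psf)))
  else read_psf(cfg$psf)
}

#' Run the full analysis pipeline
#'
#' End-to-end batch driver: load the two indicator channels (or split a
#' dual-view recording), register and background-subtract them, optionally
#' deconvolve, segment and track the cells, bleach-correct, compute the
#' ratio sequence, extract centered per-cell ROIs, shape-normalize, detect
#' microdomains, summarize at the group level, and build the dartboard
#' projection. Per-cell failures are logged and skipped; the run fails only
#' when no cell at all could be analyzed.
#'
#' Tracks are matched to bead contacts by nearest starting centroid when the
#' sidecar provides `centroid_y`/`centroid_x` columns, otherwise by order.
#'
#' @param config path to YAML or named list (see [default_config]).
#' @param write write output files to `out_dir` (default TRUE).
#' @return (invisibly) list: `tracks`, `cells` (per-cell results), `group`
#'   ([aggregate_group] output), `accumulator` (dartboard), `config`, `log`.
#' @export
run_pipeline <- function(config = list(), write = TRUE) {
  cfg <- load_config(config)
  log <- character(0)
  say <- function(...) {
    msg <- sprintf(...)
    log <<- c(log, sprintf("[%s] %s", format(Sys.time(), "%H:%M:%S"), msg))
    message(msg)
  }
  out <- cfg$out_dir
  if (write && !dir.exists(out)) dir.create(out, recursive = TRUE)

  # ---- load ----------------------------------------------------------
  if (!is.null(cfg$input_raw)) {
    raw <- read_tiff_sequence(cfg$input_raw, cfg$pixel_size_um,
                              cfg$frame_interval_s)
    pair <- split_dual_view(raw, cfg$dual_view_layout)
  } else if (!is.null(cfg$input_ch1) && !is.null(cfg$input_ch2)) {
    pair <- channel_pair(
      read_tiff_sequence(cfg$input_ch1, cfg$pixel_size_um,
                         cfg$frame_interval_s),
      read_tiff_sequence(cfg$input_ch2, cfg$pixel_size_um,
                         cfg$frame_interval_s))
  } else stop("config must name input_ch1+input_ch2 or input_raw",
              call. = FALSE)
  if (is.null(cfg$contacts))
    stop("config must name a bead-contact sidecar CSV (`contacts`)",
         call. = FALSE)
  contacts <- read_bead_contacts(cfg$contacts)
  sidecar <- utils::read.csv(cfg$contacts)
  say("loaded %d frame(s), %d bead contact(s)", n_frames(pair$ch1),
      length(contacts))

  # ---- registration --------------------------------------------------
  if (cfg$register_mode != "none") {
    if (cfg$register_mode == "first_frame") {
      tf <- register_channels(get_frame(pair$ch1, 1L),
                              get_frame(pair$ch2, 1L))
      pair$ch2 <- apply_transform(pair$ch2, tf)
    } else {
      tfs <- lapply(seq_len(n_frames(pair$ch1)), function(t)
        register_channels(get_frame(pair$ch1, t), get_frame(pair$ch2, t)))
      pair$ch2 <- apply_transform(pair$ch2, tfs, mode = "per-frame")
    }
    say("registered channels (%s)", cfg$register_mode)
  }

  # ---- background ----------------------------------------------------
  if (cfg$background_mode != "none") {
    for (ch in c("ch1", "ch2")) {
      bg <- estimate_background(pair[[ch]], cfg$background_mode,
                                cfg$background_percentile,
                                cfg$background_roi, cfg$background_value)
      pair[[ch]] <- subtract_background(pair[[ch]], bg)
    }
    say("background subtracted (%s)", cfg$background_mode)
  }

  # ---- deconvolution -------------------------------------------------
  if (cfg$deconvolve == "lucy_richardson") {
    k <- resolve_psf(cfg)
    pair$ch1 <- lucy_richardson(pair$ch1, k, cfg$lr_iterations)
    pair$ch2 <- lucy_richardson(pair$ch2, k, cfg$lr_iterations)
    say("Lucy-Richardson deconvolution, %d iteration(s)", cfg$lr_iterations)
  }

  # ---- segmentation & tracking --------------------------------------
  dets <- segment_sequence(pair$ch1, backend = cfg$seg_backend,
                           min_area_px = cfg$min_area_px)
  min_frames <- cfg$min_frames
  if (is.null(min_frames)) {
    # frames spanning 1 s before to 15 s after the earliest contact
    cf <- min(vapply(contacts, function(b) b$contact_frame, 0L))
    dt <- pair$ch1$frame_interval_s
    min_frames <- min(n_frames(pair$ch1),
                      ceiling(16 / dt) + 1L)
    min_frames <- max(1L, min(min_frames, n_frames(pair$ch1) - cf + 1L +
                                ceiling(1 / dt)))
  }
  tracks <- link_tracks(dets, max_disp = cfg$max_disp_px,
                        min_frames = min_frames, max_gap = cfg$max_gap)
  if (length(tracks) == 0L)
    stop("no cells tracked in the input", call. = FALSE)
  say("tracked %d cell(s) (min_frames=%d)", length(tracks), min_frames)

  # ---- bleaching correction -----------------------------------------
  if (cfg$bleach_mode != "none") {
    nT <- n_frames(pair$ch1)
    union_masks <- lapply(seq_len(nT), function(t) {
      m <- matrix(FALSE, dim(pair$ch1$data)[2L], dim(pair$ch1$data)[3L])
      for (tr in tracks) for (d in tr$detections)
        if (d$frame == t) m <- m | d$mask
      if (!any(m)) m[] <- TRUE  # no cell this frame: fall back to whole frame
      m
    })
    chs <- if (cfg$bleach_channel == "both") c("ch1", "ch2")
           else cfg$bleach_channel
    for (ch in chs) {
      pair[[ch]] <- switch(
        cfg$bleach_mode,
        additive = correct_bleaching_additive(pair[[ch]], union_masks),
        multiplicative = correct_bleaching_multiplicative(pair[[ch]],
                                                          union_masks),
        biexp = correct_bleaching_biexponential(pair[[ch]], union_masks)$seq,
        stop("unknown bleach_mode", call. = FALSE))
    }
    say("bleaching correction (%s) on %s", cfg$bleach_mode,
        cfg$bleach_channel)
  }

  # ---- ratio ---------------------------------------------------------
  neg <- pair$ch2$data < 0
  if (any(neg)) pair$ch2$data[neg] <- 0
  clip <- if (!is.null(cfg$ratio_clip_lo))
    c(cfg$ratio_clip_lo, cfg$ratio_clip_hi) else NULL
  ratio <- compute_ratio(pair, clip = clip)
  say("ratio computed")

  # ---- per-cell analysis --------------------------------------------
  # match tracks to contacts
  has_pos <- all(c("centroid_y", "centroid_x") %in% names(sidecar))
  cell_results <- list()
  summaries <- list()
  all_events <- list()
  for (k in seq_along(tracks)) {
    tr <- tracks[[k]]
    res <- tryCatch({
      if (has_pos) {
        d0 <- tr$detections[[1L]]$centroid
        ci <- which.min((sidecar$centroid_y - d0[1])^2 +
                          (sidecar$centroid_x - d0[2])^2)
      } else ci <- if (k <= nrow(sidecar)) k else
        stop("more tracks than bead contacts")
      contact <- contacts[[ci]]
      trace <- extract_roi(ratio, tr, pad_px = cfg$roi_pad_px)
      if (cfg$shape_norm)
        trace <- normalize_trace(trace, c_factor = cfg$scale_factor_c)
      series <- detect_trace_microdomains(
        trace, threshold = cfg$threshold, min_size = cfg$min_size,
        max_size = cfg$max_size, connectivity = cfg$connectivity)
      summ <- summarize_cell(series, contact,
                             window = c(cfg$window_pre_s, cfg$window_post_s),
                             min_active_frames = cfg$min_active_frames)
      d <- dim(trace$roi$data)
      center <- c((d[2L] + 1) / 2, (d[3L] + 1) / 2)
      R_t <- if (!is.null(trace$template_radius)) trace$template_radius
             else stats::median(vapply(seq_along(trace$frames), function(i)
               sqrt(sum(trace$masks[[i]]) / pi), 0))
      ev <- align_domains(series, contact, center, R_t,
                          cfg$reference_angle)
      list(track = tr, contact = contact, trace = trace, series = series,
           summary = summ, events = ev)
    }, error = function(e) {
      say("cell (track %d) failed: %s", tr$id, conditionMessage(e))
      NULL
    })
    if (!is.null(res)) {
      cell_results[[length(cell_results) + 1L]] <- res
      summaries[[length(summaries) + 1L]] <- res$summary
      all_events[[length(all_events) + 1L]] <- res$events
    }
  }
  if (!length(cell_results))
    stop("no cell could be analyzed", call. = FALSE)
  say("analyzed %d of %d tracked cell(s)", length(cell_results),
      length(tracks))

  group <- aggregate_group(summaries)
  geom <- dartboard_geometry(cfg$n_segments, cfg$n_rings, cfg$bullseye_frac)
  events <- do.call(rbind, all_events)
  acc <- dartboard_accumulate(events, geom, cfg$time_bins,
                              n_cells = length(cell_results),
                              reference_angle = cfg$reference_angle)
  say("dartboard: %d event(s) assigned over %d bin(s)", sum(acc$counts),
      nrow(acc$time_bins))

  # ---- outputs -------------------------------------------------------
  if (write) {
    yaml::write_yaml(cfg[!vapply(cfg, is.null, TRUE)],
                     file.path(out, "resolved_config.yaml"))
    for (i in seq_along(cell_results)) {
      res <- cell_results[[i]]
      id <- res$contact$cell_id
      write_tiff_sequence(res$trace$roi,
                          file.path(out, sprintf("cell_%s_roi.tif", id)),
                          "float32")
      utils::write.csv(domain_table(res$series, res$contact),
                       file.path(out, sprintf("cell_%s_domains.csv", id)),
                       row.names = FALSE)
    }
    cellcsv <- do.call(rbind, lapply(cell_results, function(res)
      data.frame(cell_id = res$contact$cell_id,
                 activated = res$summary$activated,
                 mean_domains_per_frame =
                   res$summary$mean_domains_per_frame)))
    utils::write.csv(cellcsv, file.path(out, "cells.csv"),
                     row.names = FALSE)
    utils::write.csv(group$timepoints, file.path(out, "group_timepoints.csv"),
                     row.names = FALSE)
    utils::write.csv(dartboard_table(acc), file.path(out, "dartboard.csv"),
                     row.names = FALSE)
    grDevices::pdf(file.path(out, "dartboard.pdf"), width = 4 * 3,
                   height = 4)
    graphics::par(mfrow = c(1, nrow(acc$time_bins)))
    for (b in seq_len(nrow(acc$time_bins))) render_dartboard(acc, b)
    grDevices::dev.off()
    writeLines(log, file.path(out, "pipeline.log"))
    say("outputs written to %s", out)
  }
  invisible(list(tracks = tracks, cells = cell_results, group = group,
                 accumulator = acc, config = cfg, log = log))
}
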