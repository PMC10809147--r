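test_that("clock positions map to the documented angles", {
  expect_equal(clock_to_angle(3), 0)
  expect_equal(clock_to_angle(12), pi / 2)
  expect_equal(clock_to_angle(6), 3 * pi / 2)
  expect_equal(clock_to_angle(9), pi)
  # fractional hour, straight from the formula
  expect_equal(clock_to_angle(7.5), (pi / 2 - 7.5 * pi / 6) %% (2 * pi))
  expect_equal(clock_to_angle(7.5), 5 * pi / 4)
  expect_error(clock_to_angle(0), "0, 12")
  expect_error(clock_to_angle(12.5), "0, 12")
})

test_that("dartboard annuli are exactly equal in area", {
  g <- dartboard_geometry(n_segments = 12, n_rings = 5, bullseye_frac = 0.2)
  # closed-form radii
  expect_equal(g$ring_radii,
               sqrt(0.2^2 + (1:5) * (1 - 0.2^2) / 5), tolerance = 1e-15)
  radii <- c(g$bullseye_frac, g$ring_radii)
  areas <- pi * diff(radii^2)
  expect_equal(max(areas) / min(areas), 1, tolerance = 1e-12)
  # total area = pi R^2
  expect_equal(g$bullseye_area + sum(areas), pi, tolerance = 1e-12)
  expect_equal(g$segment_area * g$n_segments, areas[1], tolerance = 1e-12)
})

test_that("assign_segment places the worked example and the edges", {
  g3 <- dartboard_geometry(n_segments = 12, n_rings = 3, bullseye_frac = 0.2)
  # boundaries sqrt(0.36)=0.6, sqrt(0.68), 1; r=0.7 -> ring 2
  expect_equal(assign_segment(0.7, 0, g3)$ring, 2L)
  expect_equal(assign_segment(0, 1.3, g3)$ring, 0L)       # bullseye
  expect_equal(assign_segment(0.19, 0, g3)$ring, 0L)
  expect_equal(assign_segment(0.2, 0, g3)$ring, 1L)
  expect_equal(assign_segment(1, 0, g3)$ring, 3L)
  # segment 1 is centered on the reference angle
  expect_equal(assign_segment(0.7, 0, g3)$segment, 1L)
  expect_equal(assign_segment(0.7, pi / 12 - 1e-9, g3)$segment, 1L)
  expect_equal(assign_segment(0.7, pi / 12 + 1e-9, g3)$segment, 2L)
  expect_equal(assign_segment(0.7, pi, g3)$segment, 7L)
  expect_warning(out <- assign_segment(1.2, 0, g3), "clipped")
  expect_equal(out$ring, 3L)
})

test_that("uniform disk points fill segments proportionally to area", {
  set.seed(2024)
  n <- 1e5
  r <- sqrt(stats::runif(n))
  th <- stats::runif(n, 0, 2 * pi)
  g <- dartboard_geometry(12, 5, 0.2)
  asg <- assign_segment(r, th, g)
  counts <- table(paste(asg$ring, asg$segment))
  # bullseye expectation
  exp_bull <- n * g$bullseye_frac^2
  expect_lt(abs(sum(asg$ring == 0) - exp_bull) / exp_bull, 0.05)
  # non-bullseye segments all share the same area; ring totals are large
  # enough for a tight relative bound, and the per-segment uniformity is
  # confirmed by a chi-squared test (max over 60 cells of ~1600 counts has
  # a ~2.5% standard error, so a raw 5% max-bound would be underpowered)
  seg_counts <- table(paste(asg$ring[asg$ring > 0], asg$segment[asg$ring > 0]))
  expect_equal(length(seg_counts), 5L * 12L)
  exp_seg <- n * g$segment_area / pi
  expect_gt(stats::chisq.test(as.vector(seg_counts))$p.value, 0.01)
  ring_counts <- table(asg$ring[asg$ring > 0])
  exp_ring <- exp_seg * 12
  expect_lt(max(abs(ring_counts - exp_ring)) / exp_ring, 0.05)
})

test_that("alignment sends the contact direction to the reference angle", {
  mk_series <- function(y, x, frame = 5L) {
    dom <- structure(list(frame = frame, pixels = cbind(y, x),
                          centroid = c(y, x), area_px = 1L,
                          mean_rel_intensity = 3, max_rel_intensity = 3),
                     class = "microdomain")
    structure(list(domains = list(list(dom)), frames = frame,
                   frame_interval_s = 0.5), class = "domain_time_series")
  }
  ctr <- c(50, 50); R <- 20
  for (clock in c(12, 3, 6, 7.5)) {
    a <- clock_to_angle(clock)
    s <- mk_series(ctr[1] - 15 * sin(a), ctr[2] + 15 * cos(a))
    ev <- align_domains(s, bead_contact("c", 5L, clock), ctr, R,
                        reference_angle = pi / 2)
    expect_equal(ev$theta_aligned, pi / 2, tolerance = 1e-9)
    expect_equal(ev$r_frac, 15 / 20, tolerance = 1e-9)
    expect_equal(ev$t_rel_s, 0)
  }
  # worked example: contact at clock 12, domain at image angle pi, ref pi/2
  s <- mk_series(ctr[1], ctr[2] - 12)
  ev <- align_domains(s, bead_contact("c", 5L, 12), ctr, R,
                      reference_angle = pi / 2)
  expect_equal(ev$theta_aligned, pi, tolerance = 1e-9)
  # domain at board center
  s0 <- mk_series(ctr[1], ctr[2])
  expect_equal(align_domains(s0, bead_contact("c", 5L, 4), ctr, R)$r_frac, 0)
})

test_that("aligned assignments are equivariant under joint rotation", {
  g <- dartboard_geometry(12, 5, 0.2)
  ctr <- c(40, 40); R <- 25
  set.seed(55)
  for (i in 1:20) {
    th0 <- stats::runif(1, 0, 2 * pi)
    rfr <- stats::runif(1, 0.05, 0.99)
    clock <- stats::runif(1, 1e-6, 12)
    shift_h <- sample(1:11, 1)  # rotate both by whole clock hours
    mk <- function(clk, th) {
      dom <- structure(list(frame = 3L, pixels = cbind(1, 1),
                            centroid = c(ctr[1] - rfr * R * sin(th),
                                         ctr[2] + rfr * R * cos(th)),
                            area_px = 1L, mean_rel_intensity = 2,
                            max_rel_intensity = 2), class = "microdomain")
      s <- structure(list(domains = list(list(dom)), frames = 3L,
                          frame_interval_s = 1), class = "domain_time_series")
      ev <- align_domains(s, bead_contact("c", 3L,
                                          ((clk - 1e-9) %% 12) + 1e-9),
                          ctr, R)
      assign_segment(ev$r_frac, ev$theta_aligned, g)
    }
    a1 <- mk(clock, th0)
    a2 <- mk(clock + shift_h, th0 - shift_h * pi / 6)
    expect_equal(a1, a2)
  }
})

test_that("accumulation counts, normalizes and stays linear", {
  g <- dartboard_geometry(12, 5, 0.2)
  ev <- data.frame(cell_id = "a", t_rel_s = 2, r_frac = 0.05,
                   theta_aligned = 1)
  acc <- dartboard_accumulate(ev, g, n_cells = 1)
  expect_equal(sum(acc$counts), 1L)
  expect_equal(acc$counts[1, 1, 1], 1L)
  expect_equal(acc$densities[1, 1, 1], 1 / (g$bullseye_area * 5 * 1))
  # empty events -> all zero
  acc0 <- dartboard_accumulate(ev[0, ], g, n_cells = 2)
  expect_true(all(acc0$densities == 0))
  # doubling events doubles densities
  acc2 <- dartboard_accumulate(rbind(ev, ev), g, n_cells = 1)
  expect_equal(acc2$densities, 2 * acc$densities)
  # count conservation per bin with events outside the bins dropped
  set.seed(9)
  evs <- data.frame(cell_id = "a", t_rel_s = stats::runif(200, -2, 20),
                    r_frac = stats::runif(200), theta_aligned =
                      stats::runif(200, 0, 2 * pi))
  accs <- dartboard_accumulate(evs, g, n_cells = 4)
  in_window <- sum(evs$t_rel_s >= 0 & evs$t_rel_s < 15)
  expect_equal(sum(accs$counts), in_window)
  expect_error(dartboard_accumulate(evs, g,
                                    time_bins = list(c(0, 5), c(4, 8)),
                                    n_cells = 1), "overlap")
  expect_error(dartboard_accumulate(evs, g, n_cells = 0), "n_cells")
})

test_that("moving averages spread impulses and keep constants", {
  g <- dartboard_geometry(4, 2, 0.3)
  bins <- lapply(0:8, function(i) c(i, i + 1))
  # one event in bin 5, ring 1 segment 2
  ev <- data.frame(cell_id = "a", t_rel_s = 4.5, r_frac = 0.5,
                   theta_aligned = pi / 2)
  acc <- dartboard_accumulate(ev, g, bins, n_cells = 1)
  sm <- moving_average_densities(acc, window_s = 3)
  series <- sm[, 2, 2]
  d0 <- acc$densities[5, 2, 2]
  expect_equal(series[4:6], rep(d0 / 3, 3))
  expect_equal(sum(series[-c(4:6)]), 0)
  # interior sum preserved
  expect_equal(sum(series), d0, tolerance = 1e-12)
  # constant densities unchanged
  evs <- do.call(rbind, lapply(0:8 + 0.5, function(t0)
    data.frame(cell_id = "a", t_rel_s = t0, r_frac = 0.5,
               theta_aligned = pi / 2)))
  accc <- dartboard_accumulate(evs, g, bins, n_cells = 1)
  smc <- moving_average_densities(accc, window_s = 3)
  expect_equal(smc, accc$densities)
  expect_error(moving_average_densities(acc, 0.5), "at least")
})

test_that("rendering is deterministic and encodes densities in color", {
  g <- dartboard_geometry(6, 2, 0.25)
  ev <- data.frame(cell_id = "a", t_rel_s = 1, r_frac = 0.6,
                   theta_aligned = 0)
  acc <- dartboard_accumulate(ev, g, n_cells = 1)
  tf <- tempfile(fileext = ".pdf")
  grDevices::pdf(tf)
  cols <- render_dartboard(acc, 1)
  cols2 <- render_dartboard(acc, 1)
  grDevices::dev.off()
  expect_identical(cols, cols2)
  # exactly one wedge carries the hot color
  hot <- which(cols == cols[acc$counts[1, , ] == 1])
  expect_length(hot, 1L)
  # all-zero board: uniform minimum color
  acc0 <- dartboard_accumulate(ev[0, ], g, n_cells = 1)
  grDevices::pdf(tf)
  cols0 <- render_dartboard(acc0, 1)
  grDevices::dev.off()
  expect_length(unique(as.vector(cols0)), 1L)
  unlink(tf)
})

test_that("bead-contact sidecar files round trip", {
  tmp <- withr::local_tempdir()
  df <- data.frame(cell_id = c("a", "b"), contact_frame = c(4L, 6L),
                   clock_position = c(12, 7.5))
  utils::write.csv(df, file.path(tmp, "contacts.csv"), row.names = FALSE)
  bcs <- read_bead_contacts(file.path(tmp, "contacts.csv"))
  expect_length(bcs, 2L)
  expect_equal(bcs[["b"]]$clock_position, 7.5)
  expect_error(read_bead_contacts(file.path(tmp, "missing.csv")),
               "not found")
  utils::write.csv(data.frame(x = 1), file.path(tmp, "bad.csv"),
                   row.names = FALSE)
  expect_error(read_bead_contacts(file.path(tmp, "bad.csv")), "columns")
  expect_error(bead_contact("a", 1L, 13), "0, 12")
})
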