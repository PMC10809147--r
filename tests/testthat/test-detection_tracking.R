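test_that("a single bright disk is segmented with the right area", {
  d <- disk_frame(64, 64, 32, 30, 10, inside = 100, outside = 5)
  dets <- segment_frame(d$frame, min_area_px = 30)
  expect_length(dets, 1L)
  expect_lt(abs(dets[[1]]$area_px - pi * 100) / (pi * 100), 0.05)
  expect_lt(max(abs(dets[[1]]$centroid - c(32, 30))), 1)
})

test_that("two separated disks give two detections at the right centroids", {
  a <- disk_frame(64, 64, 20, 18, 8, inside = 100, outside = 5)
  b <- disk_frame(64, 64, 45, 44, 8, inside = 100, outside = 5)
  f <- pmax(a$frame, b$frame)
  dets <- segment_frame(f, min_area_px = 30)
  expect_length(dets, 2L)
  cents <- t(vapply(dets, function(d) d$centroid, numeric(2)))
  cents <- cents[order(cents[, 1]), ]
  expect_lt(max(abs(cents - rbind(c(20, 18), c(45, 44)))), 1)
})

test_that("blank frames give no detections and masks are disjoint", {
  expect_length(segment_frame(matrix(3, 32, 32)), 0L)
  a <- disk_frame(64, 64, 20, 20, 9, inside = 80, outside = 2)
  b <- disk_frame(64, 64, 40, 44, 9, inside = 80, outside = 2)
  dets <- segment_frame(pmax(a$frame, b$frame), min_area_px = 20)
  if (length(dets) >= 2)
    expect_equal(sum(dets[[1]]$mask & dets[[2]]$mask), 0L)
})

make_det <- function(frame, y, x, label = 1L) {
  mask <- matrix(FALSE, 64, 64); mask[y, x] <- TRUE
  structure(list(frame = frame, label = label, centroid = c(y, x),
                 area_px = 1L, mask = mask,
                 boundary = cbind(y = y, x = x)), class = "cell_detection")
}

test_that("a stationary blob yields one full-length track", {
  dets <- lapply(1:10, function(t) list(make_det(t, 30, 30)))
  trk <- link_tracks(dets, max_disp = 5)
  expect_length(trk, 1L)
  expect_length(trk[[1]]$detections, 10L)
  expect_equal(trk[[1]]$frame_span, c(1L, 10L))
})

test_that("min_frames filters short tracks", {
  dets <- c(lapply(1:3, function(t) list(make_det(t, 30, 30))),
            lapply(4:10, function(t) list()))
  expect_length(link_tracks(dets, max_disp = 5, min_frames = 5), 0L)
  expect_length(link_tracks(dets, max_disp = 5, min_frames = 3), 1L)
})

test_that("crossing paths are linked like the brute-force matching oracle", {
  # two blobs on crossing linear paths
  pos <- function(t) rbind(c(10 + 3 * t, 20 + 2 * t),
                           c(40 - 3 * t, 20 + 2 * t))
  dets <- lapply(0:9, function(t) {
    p <- pos(t)
    list(make_det(t + 1L, p[1, 1], p[1, 2], 1L),
         make_det(t + 1L, p[2, 1], p[2, 2], 2L))
  })
  trk <- link_tracks(dets, max_disp = 6)
  expect_length(trk, 2L)
  expect_true(all(vapply(trk, function(x) length(x$detections), 0L) == 10L))
  # every consecutive link agrees with the exhaustive minimal-cost matching
  for (t in 1:9) {
    from <- pos(t - 1); to <- pos(t)
    expect_equal(oracle_match(from, to, 6), c(1L, 2L))
  }
  # and the tracks follow those assignments (no identity swap at crossing)
  ys <- vapply(trk[[1]]$detections, function(d) d$centroid[1], 0)
  expect_true(all(diff(ys) > 0) || all(diff(ys) < 0))
})

test_that("linking is invariant to detection order within a frame", {
  dets1 <- lapply(1:5, function(t)
    list(make_det(t, 10 + t, 10), make_det(t, 40 - t, 40)))
  dets2 <- lapply(dets1, rev)
  t1 <- link_tracks(dets1, max_disp = 4)
  t2 <- link_tracks(dets2, max_disp = 4)
  sig <- function(trks) sort(vapply(trks, function(tr)
    paste(vapply(tr$detections, function(d)
      sprintf("%d:%g,%g", d$frame, d$centroid[1], d$centroid[2]), ""),
      collapse = ";"), ""))
  expect_equal(sig(t1), sig(t2))
})

test_that("gaps up to max_gap are bridged", {
  dets <- lapply(1:7, function(t)
    if (t %in% c(3, 4)) list() else list(make_det(t, 25, 25)))
  trk <- link_tracks(dets, max_disp = 5, max_gap = 2)
  expect_length(trk, 1L)
  expect_length(trk[[1]]$detections, 5L)
  trk0 <- link_tracks(dets, max_disp = 5, max_gap = 1)
  expect_length(trk0, 2L)
})

test_that("extract_roi keeps the cell centered to within a pixel", {
  # cell drifting +1 px/frame in x on a quiet background
  nT <- 8
  arr <- array(2, dim = c(nT, 64, 64))
  dets <- vector("list", nT)
  for (t in 1:nT) {
    d <- disk_frame(64, 64, 30, 20 + t, 7, inside = 90, outside = 2)
    arr[t, , ] <- d$frame
    idx <- which(d$mask, arr.ind = TRUE)
    dets[[t]] <- list(structure(
      list(frame = t, label = 1L, centroid = c(mean(idx[, 1]), mean(idx[, 2])),
           area_px = sum(d$mask), mask = d$mask,
           boundary = circle_boundary(30, 20 + t, 7, 36)),
      class = "cell_detection"))
  }
  fs <- frame_sequence(arr)
  trk <- link_tracks(dets, max_disp = 3)[[1]]
  trace <- extract_roi(fs, trk, pad_px = 3)
  d <- dim(trace$roi$data)
  ctr <- c((d[2] + 1) / 2, (d[3] + 1) / 2)
  for (i in seq_len(d[1])) {
    idx <- which(trace$masks[[i]], arr.ind = TRUE)
    cen <- c(mean(idx[, 1]), mean(idx[, 2]))
    expect_lt(max(abs(cen - ctr)), 1)
    # boundary was shifted by exactly the recorded integer offset
    orig <- circle_boundary(30, 20 + trace$frames[i], 7, 36)
    expect_equal(trace$boundaries[[i]],
                 orig - matrix(trace$offsets[i, ], 36, 2, byrow = TRUE),
                 ignore_attr = TRUE)
  }
  # stationary cell: ROI equals a fixed crop each frame
  arr2 <- array(0, dim = c(3, 64, 64))
  d0 <- disk_frame(64, 64, 32, 32, 8, inside = 50, outside = 1)
  for (t in 1:3) arr2[t, , ] <- d0$frame * t
  dets2 <- lapply(1:3, function(t) {
    idx <- which(d0$mask, arr.ind = TRUE)
    list(structure(list(frame = t, label = 1L,
                        centroid = c(mean(idx[, 1]), mean(idx[, 2])),
                        area_px = sum(d0$mask), mask = d0$mask,
                        boundary = circle_boundary(32, 32, 8, 36)),
                   class = "cell_detection"))
  })
  tr2 <- extract_roi(frame_sequence(arr2), link_tracks(dets2, 3)[[1]], 2)
  h2 <- dim(tr2$roi$data)[2]; w2 <- dim(tr2$roi$data)[3]
  o <- tr2$offsets[1, ]
  for (t in 1:3)
    expect_equal(get_frame(tr2$roi, t),
                 arr2[t, o[1] + seq_len(h2), o[2] + seq_len(w2)])
  # oversized ROI errors
  big <- disk_frame(20, 20, 10, 10, 8, inside = 10, outside = 0)
  idx <- which(big$mask, arr.ind = TRUE)
  det_big <- list(list(structure(
    list(frame = 1L, label = 1L, centroid = c(10, 10), area_px = sum(big$mask),
         mask = big$mask, boundary = circle_boundary(10, 10, 8, 36)),
    class = "cell_detection")))
  trk_big <- link_tracks(det_big, 3)[[1]]
  expect_error(extract_roi(frame_sequence(matrix(1, 20, 20)), trk_big,
                           pad_px = 5), "larger")
})
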