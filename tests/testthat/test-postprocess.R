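# textured test image with enough structure for registration
reg_image <- function(seed = 1) {
  set.seed(seed)
  f <- blob_frame(64, 64, rbind(c(30, 34), c(45, 20), c(20, 48)),
                  sigma = 5, amp = c(1))
  f + blob_frame(64, 64, rbind(c(38, 50)), sigma = 3, amp = 0.6)
}

test_that("registration returns identity for already-aligned images", {
  f <- reg_image()
  tf <- register_channels(f, f)
  expect_lt(max(abs(tf$offset)), 0.1)
  expect_lt(max(abs(tf$matrix - diag(2))), 0.01)
})

test_that("registration recovers known shifts within 0.25 px", {
  f <- reg_image()
  for (sh in list(c(3, -2), c(-1.5, 2.5))) {
    # moving(p) = fixed(p - sh): content shifted by +sh
    moving <- microdart:::warp_frame(f, affine_transform2d(diag(2), sh))
    tf <- register_channels(f, moving, mode = "translation")
    # the registering transform must undo the shift: offset = -sh
    expect_lt(max(abs(tf$offset + sh)), 0.25)
  }
})

test_that("registration recovers a small rotation within 0.5 degrees", {
  f <- reg_image()
  a <- 2 * pi / 180
  R <- matrix(c(cos(a), sin(a), -sin(a), cos(a)), 2, 2)
  ctr <- c(32.5, 32.5)
  tf_true <- affine_transform2d(R, ctr - R %*% ctr)
  moving <- microdart:::warp_frame(f, tf_true)
  tf <- register_channels(f, moving)
  # recovered transform is the inverse rotation (-a)
  rec_angle <- atan2(tf$matrix[2, 1], tf$matrix[1, 1])
  expect_lt(abs(rec_angle - (-a)) * 180 / pi, 0.5)
})

test_that("registration rejects constant images", {
  expect_error(register_channels(matrix(1, 8, 8), matrix(1, 8, 8)),
               "constant")
})

test_that("apply_transform matches an explicit index-shift for integer shifts", {
  set.seed(3)
  fs <- frame_sequence(array(stats::runif(2 * 20 * 24), dim = c(2, 20, 24)))
  tf <- affine_transform2d(diag(2), c(2, -3))
  out <- apply_transform(fs, tf, interpolation = "nearest")
  # oracle: out(y, x) = in(y - 2, x + 3), zero outside
  for (t in 1:2) {
    expected <- matrix(0, 20, 24)
    for (y in 1:20) for (x in 1:24) {
      sy <- y - 2; sx <- x + 3
      if (sy >= 1 && sy <= 20 && sx >= 1 && sx <= 24)
        expected[y, x] <- fs$data[t, sy, sx]
    }
    expect_equal(get_frame(out, t), expected)
  }
  # identity
  id <- apply_transform(fs, affine_transform2d())
  expect_equal(id$data, fs$data, tolerance = 1e-12)
  # per-frame mode validates the list length
  expect_error(apply_transform(fs, list(tf), mode = "per-frame"), "2")
})

test_that("two half-pixel shifts compose to one full-pixel shift", {
  f <- blob_frame(48, 48, rbind(c(24, 24)), sigma = 8)
  fs <- frame_sequence(array(f, dim = c(1, 48, 48)))
  half <- affine_transform2d(diag(2), c(0.5, 0))
  once <- apply_transform(apply_transform(fs, half), half)
  full <- apply_transform(fs, affine_transform2d(diag(2), c(1, 0)))
  inner <- get_frame(once, 1)[5:44, 5:44] - get_frame(full, 1)[5:44, 5:44]
  expect_lt(max(abs(inner)), 0.01)
})

test_that("background subtraction clips at zero and estimates percentiles", {
  fs <- frame_sequence(array(10, dim = c(2, 8, 8)))
  expect_true(all(subtract_background(fs, 4)$data == 6))
  expect_true(all(subtract_background(fs, 99)$data == 0))
  expect_error(subtract_background(fs, -1), ">= 0")
  # two-level frame: 1st percentile picks the background level
  f <- matrix(5, 20, 20); f[5:15, 5:15] <- 50
  fs2 <- frame_sequence(array(f, dim = c(1, 20, 20)))
  expect_equal(estimate_background(fs2, "percentile", percentile = 1), 5)
  # property: never negative under random backgrounds
  set.seed(9)
  r <- frame_sequence(array(stats::runif(3 * 6 * 6, 0, 4), dim = c(3, 6, 6)))
  expect_true(all(subtract_background(r, c(1, 3, 5))$data >= 0))
})

test_that("ratio computation masks zero denominators and matches a loop", {
  mk <- function(x) frame_sequence(array(x, dim = c(2, 4, 4)))
  p <- channel_pair(mk(2), mk(1))
  expect_true(all(compute_ratio(p)$data == 2))
  # zero denominator pixel -> 0, never NaN/Inf
  ch2 <- array(1, dim = c(1, 3, 3)); ch2[1, 2, 2] <- 0
  p2 <- channel_pair(frame_sequence(array(5, dim = c(1, 3, 3))),
                     frame_sequence(ch2))
  r2 <- compute_ratio(p2)
  expect_equal(r2$data[1, 2, 2], 0)
  expect_true(all(is.finite(r2$data)))
  # random stacks against the elementwise oracle
  set.seed(11)
  a <- array(stats::runif(2 * 5 * 5, 0.1, 9), dim = c(2, 5, 5))
  b <- array(stats::runif(2 * 5 * 5, 0.1, 9), dim = c(2, 5, 5))
  r <- compute_ratio(channel_pair(frame_sequence(a), frame_sequence(b)))
  oracle <- array(0, dim = dim(a))
  for (i in seq_along(a)) oracle[i] <- a[i] / b[i]
  expect_equal(r$data, oracle)
  # clipping
  rc <- compute_ratio(channel_pair(frame_sequence(a), frame_sequence(b)),
                      clip = c(0.5, 2))
  expect_true(all(rc$data >= 0.5 & rc$data <= 2))
})

test_that("additive bleaching correction applies the hand-computed offsets", {
  arr <- array(0, dim = c(3, 4, 4))
  arr[1, , ] <- 10; arr[2, , ] <- 8; arr[3, , ] <- 6
  fs <- frame_sequence(arr)
  mask <- matrix(TRUE, 4, 4)
  out <- correct_bleaching_additive(fs, mask, target_mean = 10)
  expect_equal(out$data[1, 1, 1], 10)
  expect_equal(out$data[2, 1, 1], 10)  # offset +2
  expect_equal(out$data[3, 1, 1], 10)  # offset +4
  # constant stack, target equal to mean: unchanged
  c5 <- frame_sequence(array(5, dim = c(2, 3, 3)))
  expect_equal(correct_bleaching_additive(c5, matrix(TRUE, 3, 3),
                                          target_mean = 5)$data, c5$data)
  # empty mask errors with the frame index
  m <- list(matrix(TRUE, 3, 3), matrix(FALSE, 3, 3))
  expect_error(correct_bleaching_additive(c5, m), "frame 2")
})

test_that("multiplicative correction applies the hand-computed scales", {
  arr <- array(0, dim = c(2, 4, 4))
  arr[1, , ] <- 10; arr[2, , ] <- 8
  fs <- frame_sequence(arr)
  out <- correct_bleaching_multiplicative(fs, matrix(TRUE, 4, 4),
                                          target_mean = 10)
  expect_equal(out$data[1, 1, 1], 10)        # scale 1.0
  expect_equal(out$data[2, 1, 1], 8 * 1.25)  # scale 1.25
  # doubling the target doubles the corrected stack
  out2 <- correct_bleaching_multiplicative(fs, matrix(TRUE, 4, 4),
                                           target_mean = 20)
  expect_equal(out2$data, 2 * out$data)
})

test_that("both frame-wise corrections pin the masked mean on random stacks", {
  set.seed(21)
  for (rep in 1:3) {
    arr <- array(stats::runif(4 * 10 * 10, 1, 20), dim = c(4, 10, 10))
    masks <- lapply(1:4, function(t)
      matrix(sample(c(TRUE, FALSE), 100, TRUE, prob = c(0.4, 0.6)), 10, 10))
    fs <- frame_sequence(arr)
    target <- 7.5
    for (fun in list(correct_bleaching_additive,
                     correct_bleaching_multiplicative)) {
      out <- fun(fs, masks, target_mean = target)
      mm <- vapply(1:4, function(t) mean(get_frame(out, t)[masks[[t]]]), 0)
      expect_true(all(abs(mm - target) / target < 1e-9))
    }
  }
})

test_that("biexponential fit recovers noiseless parameters within 1%", {
  t <- 0:50
  y <- 5 + 3 * exp(-t / 2) + 1 * exp(-t / 20)
  m <- fit_biexponential(y, t)
  expect_lt(abs(m$a - 5) / 5, 0.01)
  expect_lt(abs(m$b1 - 3) / 3, 0.01)
  expect_lt(abs(m$tau1 - 2) / 2, 0.01)
  expect_lt(abs(m$b2 - 1) / 1, 0.01)
  expect_lt(abs(m$tau2 - 20) / 20, 0.01)
  expect_true(m$tau1 <= m$tau2)
})

test_that("biexponential fit handles a constant trace as a no-op", {
  m <- fit_biexponential(rep(4.2, 10))
  expect_equal(m$a, 4.2, tolerance = 1e-8)
  expect_lt(abs(m$b1) + abs(m$b2), 1e-6)
})

test_that("biexponential correction flattens a noiseless decaying stack", {
  t <- (0:19) * 1.0
  curve <- 2 + 4 * exp(-t / 3) + 1.5 * exp(-t / 15)
  arr <- array(0, dim = c(20, 6, 6))
  for (i in 1:20) arr[i, , ] <- curve[i] *
      matrix(stats::runif(36, 0.9, 1.1), 6, 6)[1] # uniform frame, scaled
  # make frames exactly uniform at curve value for the closed-form check
  for (i in 1:20) arr[i, , ] <- curve[i]
  fs <- frame_sequence(arr, frame_interval_s = 1)
  res <- correct_bleaching_biexponential(fs, matrix(TRUE, 6, 6))
  means <- vapply(1:20, function(i) mean(get_frame(res$seq, i)), 0)
  expect_true(all(abs(means - means[1]) / means[1] < 1e-6))
})
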