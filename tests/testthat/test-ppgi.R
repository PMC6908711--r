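test_that("extract_ppgi is the masked spatial mean with invalid empty frames", {
  m <- matrix(FALSE, 10, 10); m[3:6, 3:6] <- TRUE
  uni <- array(100, c(10, 10, 3))
  frames <- list(uni, uni)
  attr(frames, "frame_rate") <- 20
  p <- extract_ppgi(frames, list(m, m), "green")
  expect_equal(p$x, c(100, 100))
  # excluded pixels must not contribute
  fr <- array(200, c(10, 10, 3))
  fr[, , 2][m] <- 50
  p2 <- extract_ppgi(list(fr), list(m), "green")
  expect_equal(p2$x, 50)
  # empty mask: invalid sample, no value invented
  p3 <- extract_ppgi(list(fr, fr), list(m, matrix(FALSE, 10, 10)), "green")
  expect_false(p3$valid[2])
  expect_true(is.na(p3$x[2]))
  expect_error(extract_ppgi(list(fr), list(m, m)), "masks")
  expect_error(extract_ppgi(list(fr), list(matrix(FALSE, 3, 3))), "dimensions")
})

test_that("cardiac cascade rejects DC, passes the band, and is linear", {
  fs <- 20
  t <- seq(0, 30 - 1 / fs, by = 1 / fs)
  const <- ppgi_signal(rep(7, length(t)), fs)
  out <- filter_cardiac(const)
  expect_lt(max(abs(out$x)), 1e-6 * 7)
  # band behaviour measured on the designed response
  taps <- cardiac_filter_taps(fs)
  expect_gt(fir_cascade_response(taps, 3.0, fs), 0.9)
  expect_lt(fir_cascade_response(taps, 0.5, fs), 0.1)
  # pass/stop-band contract
  pass <- fir_cascade_response(taps, seq(1.8, 4.0, by = 0.05), fs)
  expect_true(all(20 * log10(pass) >= -3))
  stop_lo <- fir_cascade_response(taps, seq(0.1, 1.0, by = 0.05), fs)
  stop_hi <- fir_cascade_response(taps, seq(5.5, 9.9, by = 0.05), fs)
  expect_true(all(20 * log10(stop_lo) <= -20))
  expect_true(all(20 * log10(stop_hi) <= -20))
  # time-domain amplitudes agree with the response oracle
  s3 <- filter_cardiac(ppgi_signal(sin(2 * pi * 3 * t), fs))
  mid <- 200:400
  expect_gt(max(abs(s3$x[mid])), 0.9)
  expect_lt(max(abs(s3$x[mid])), 1.1)
  s05 <- filter_cardiac(ppgi_signal(sin(2 * pi * 0.5 * t), fs))
  expect_lt(max(abs(s05$x[mid])), 0.1)
  # linearity
  a <- stats::rnorm(600); b <- stats::rnorm(600)
  fa <- filter_cardiac(ppgi_signal(a, fs))$x
  fb <- filter_cardiac(ppgi_signal(b, fs))$x
  fab <- filter_cardiac(ppgi_signal(a + b, fs))$x
  expect_equal(fab, fa + fb, tolerance = 1e-9)
  expect_error(filter_cardiac(ppgi_signal(rnorm(50), fs)), "filter length")
})

test_that("respiratory cascade has the stated band", {
  fs <- 20
  taps <- respiratory_filter_taps(fs)
  t <- seq(0, 40 - 1 / fs, by = 1 / fs)
  out <- filter_respiratory(ppgi_signal(rep(3, length(t)), fs))
  expect_lt(max(abs(out$x)), 1e-6 * 3)
  s1 <- filter_respiratory(ppgi_signal(sin(2 * pi * 1 * t), fs))
  mid <- 300:500
  expect_gt(max(abs(s1$x[mid])), 0.9)
  expect_lt(max(abs(s1$x[mid])), 1.1)
  s3 <- filter_respiratory(ppgi_signal(sin(2 * pi * 3 * t), fs))
  expect_lt(max(abs(s3$x[mid])), 0.1)
  expect_gt(fir_cascade_response(taps, 1.0, fs), 0.9)
  expect_lt(fir_cascade_response(taps, 3.0, fs), 0.1)
})

test_that("invalid samples propagate and short gaps are bridged", {
  fs <- 20
  t <- seq(0, 30 - 1 / fs, by = 1 / fs)
  x <- sin(2 * pi * 2 * t)
  valid <- rep(TRUE, length(x))
  valid[100:105] <- FALSE            # 0.3 s gap: bridged
  valid[300:340] <- FALSE            # 2 s gap: splits the signal
  sig <- ppgi_signal(ifelse(valid, x, NA), fs)
  out <- filter_cardiac(sig)
  expect_true(all(!out$valid[300:340]))
  expect_true(all(out$valid[100:105]))
  expect_true(any(out$valid[400:599]))
})

test_that("activity index measures mask change and flags motion seconds", {
  m <- matrix(FALSE, 20, 40); m[5:15, 5:15] <- TRUE
  same <- replicate(60, m, simplify = FALSE)
  act <- activity_index(same, frame_rate = 20)
  expect_true(all(act$frame_activity == 0))
  expect_false(any(act$active))
  # translation by half the mask width in one frame: symmetric difference
  # equals the full area
  m2 <- matrix(FALSE, 20, 40); m2[5:15, 11:21] <- TRUE
  shifted <- c(replicate(30, m, simplify = FALSE),
               replicate(30, m2, simplify = FALSE))
  act2 <- activity_index(shifted, frame_rate = 20)
  expect_gt(act2$frame_activity[31], 0.9)
  sc <- quiet_scene(duration = 30, motion_bursts = list(c(10, 15, 5)))
  act3 <- activity_index(sc$truth$get_mask, n_frames = sc$frames$n,
                         frame_rate = 20)
  burst <- act3$second >= 10 & act3$second < 15
  expect_true(all(act3$active[burst]))
  expect_false(any(act3$active[act3$second < 8 | act3$second > 17]))
})

test_that("step changes are detected without false positives on noise", {
  set.seed(1)
  x <- stats::rnorm(1200)
  x[601:1200] <- x[601:1200] + 10
  cp <- detect_step_changes(ppgi_signal(x, 20))
  expect_equal(length(cp$indices), 1)
  expect_lt(abs(cp$times - 30), 0.5)
  for (s in 2:4) {
    set.seed(s)
    cps <- detect_step_changes(ppgi_signal(stats::rnorm(1200), 20))
    expect_equal(length(cps$indices), 0)
  }
  expect_equal(length(detect_step_changes(ppgi_signal(rnorm(5), 20))$indices), 0)
})

test_that("extraction is invariant to joint frame and mask rescaling", {
  sc <- quiet_scene(duration = 5, noise_sd = 0)
  p1 <- extract_ppgi(sc$frames, sc$truth$get_mask, "green")
  upscale <- function(m) m[rep(seq_len(nrow(m)), each = 2),
                           rep(seq_len(ncol(m)), each = 2)]
  frames_big <- lapply(seq_len(sc$frames$n), function(i) {
    fr <- sc$frames$get_frame(i)
    big <- array(0, c(2 * dim(fr)[1], 2 * dim(fr)[2], 3))
    for (k in 1:3) big[, , k] <- upscale(fr[, , k])
    big
  })
  attr(frames_big, "frame_rate") <- 20
  masks_big <- lapply(seq_len(sc$frames$n),
                      function(i) upscale(sc$truth$get_mask(i)))
  p2 <- extract_ppgi(frames_big, masks_big, "green")
  expect_equal(p1$x, p2$x, tolerance = 1e-12)
})
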