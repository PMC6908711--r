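test_that("ellipse moment fit matches rasterised shapes and the EBImage oracle", {
  rast_disc <- function(r, pad = 5) {
    n <- 2 * (r + pad) + 1
    c0 <- r + pad + 1
    outer(1:n, 1:n, function(y, x) (x - c0)^2 + (y - c0)^2 <= r^2)
  }
  ef <- fit_ellipse(rast_disc(20))
  expect_true(ef$valid)
  expect_equal(ef$major, 40, tolerance = 0.02 * 40)
  expect_equal(ef$minor, 40, tolerance = 0.02 * 40)
  expect_lt(ef$eccentricity, 0.1)
  # independent oracle: EBImage moment features on the same raster
  fm <- EBImage::computeFeatures.moment(
    EBImage::bwlabel(EBImage::Image(rast_disc(20) * 1)))
  expect_equal(ef$major, unname(fm[, "m.majoraxis"]), tolerance = 0.01)
  # axis-aligned rectangle: orientation 0, major along the long side
  rect <- matrix(FALSE, 60, 100); rect[21:40, 21:80] <- TRUE
  er <- fit_ellipse(rect)
  expect_equal(er$orientation, 0, tolerance = 1e-6)
  expect_gt(er$major, er$minor)
  # rotation covariance: axes preserved, orientation shifted by pi/2
  er90 <- fit_ellipse(t(rect))
  expect_equal(er90$major, er$major, tolerance = 0.02 * er$major)
  expect_equal((er90$orientation - er$orientation) %% pi, pi / 2,
               tolerance = 1e-6)
  # translation invariance
  shifted <- matrix(FALSE, 60, 100); shifted[31:50, 31:90] <- TRUE
  es <- fit_ellipse(shifted)
  expect_equal(es$major, er$major, tolerance = 1e-9)
  expect_equal(es$eccentricity, er$eccentricity, tolerance = 1e-9)
  expect_false(fit_ellipse(matrix(FALSE, 5, 5))$valid)
})

test_that("twelve channels are produced with a shared validity pattern", {
  sc <- quiet_scene(duration = 12, rr = 60, shape_amplitude = 0.05,
                    absence_intervals = list(c(5, 7)))
  rs <- extract_resp_signals(sc$frames, sc$truth$get_mask)
  expect_length(rs, 12)
  expect_named(rs, neovitals:::RESP_CHANNELS)
  v <- rs[[1]]$valid
  for (ch in rs) expect_identical(ch$valid, v)
  absent_frames <- 101:139
  expect_true(all(!v[absent_frames]))
  # static scene: area constant, centroid constant
  sc2 <- quiet_scene(duration = 5, ppgi_amplitude = 0, shape_amplitude = 0)
  rs2 <- extract_resp_signals(sc2$frames, sc2$truth$get_mask)
  expect_lt(diff(range(rs2$skin_area$x)), 1e-9)
  expect_lt(diff(range(rs2$skin_centroid_x$x)), 1e-9)
  # minor axis modulated at the respiratory frequency
  sc3 <- quiet_scene(duration = 30, rr = 60, shape_amplitude = 0.05)
  rs3 <- extract_resp_signals(sc3$frames, sc3$truth$get_mask)
  expect_equal(periodogram_peak(rs3$ellipse_minor$x, 20, 0.3, 2), 1.0,
               tolerance = 0.05)
})

test_that("ellipse channels follow the largest connected region", {
  big <- matrix(FALSE, 40, 80); big[5:35, 5:40] <- TRUE
  small_static <- matrix(FALSE, 40, 80); small_static[10:15, 60:70] <- TRUE
  combined <- big | small_static
  ef_comb <- fit_ellipse(neovitals:::largest_component(combined))
  ef_big <- fit_ellipse(big)
  expect_equal(ef_comb$major, ef_big$major, tolerance = 1e-9)
  expect_equal(ef_comb$centre, ef_big$centre, tolerance = 1e-9)
})

test_that("both breath detectors count a 1 Hz sinusoid correctly", {
  fs <- 20
  t <- seq(0, 30 - 1 / fs, by = 1 / fs)
  sig <- ppgi_signal(sin(2 * pi * t), fs)
  expect_lte(abs(nrow(detect_breaths_mac(sig)) - 30), 1)
  expect_lte(abs(nrow(detect_breaths_bssf(sig)) - 30), 1)
  flat <- ppgi_signal(numeric(600), fs)
  expect_equal(nrow(detect_breaths_mac(flat)), 0)
  expect_equal(nrow(detect_breaths_bssf(flat)), 0)
  # 300 ms upslope window is six samples at 20 Hz
  expect_equal(ceiling(0.300 * 20), 6)
  # high-frequency ripple does not double-count (refractory)
  ripple <- ppgi_signal(sin(2 * pi * t) + 0.05 * sin(2 * pi * 9 * t), fs)
  expect_lte(abs(nrow(detect_breaths_mac(ripple)) - 30), 1)
  # refractory suppresses events closer than 500 ms
  b <- detect_breaths_bssf(ppgi_signal(sin(2 * pi * 1.8 * t), fs))
  expect_true(all(diff(b$onset) > 0.45))
})

test_that("respiratory window SQI enforces detector agreement and activity", {
  fs <- 20
  t <- seq(0, 30 - 1 / fs, by = 1 / fs)
  sig <- filter_respiratory(ppgi_signal(sin(2 * pi * t) * 10, fs))
  mac <- detect_breaths_mac(sig)
  bssf <- detect_breaths_bssf(sig)
  scored <- neovitals:::score_breaths(bssf, sig)
  win <- c(10, 20)
  sqi <- resp_window_sqi(win, mac, scored)
  expect_gt(sqi, 0.8)
  # mismatched counts: SQI exactly 0
  in_win <- which(mac$peak >= win[1] & mac$peak <= win[2])
  mac_drop <- mac[-in_win[1], ]
  expect_identical(resp_window_sqi(win, mac_drop, scored), 0)
  # equal counts inside a motion burst: activity gate forces 0
  act <- list(second = 10:19, active = rep(TRUE, 10), threshold = 0.02)
  expect_identical(resp_window_sqi(win, mac, scored, act), 0)
})

test_that("counting respiratory estimator follows the interval convention", {
  est <- rr_estimate(seq(5, 15), c(4.9, 15.1))
  expect_true(est$valid)
  expect_equal(est$value, 60)
  est2 <- rr_estimate(c(3, 8), c(0, 10))
  expect_false(est2$valid)  # 12 breaths/min, below 18
  expect_false(rr_estimate(c(3), c(0, 10))$valid)
})

test_that("per-channel estimation and fusion recover the scene rate", {
  sc <- quiet_scene(duration = 40, hr = 150, rr = 40, shape_amplitude = 0.04,
                    noise_sd = 1, flicker_sd = 0.003, seed = 17)
  rs <- extract_resp_signals(sc$frames, sc$truth$get_mask)
  act <- activity_index(sc$truth$get_mask, n_frames = sc$frames$n,
                        frame_rate = 20)
  ce <- estimate_rr_channels(rs, act)
  expect_named(ce, neovitals:::RESP_CHANNELS)
  fused <- fuse_rr(ce)
  ok <- fused$valid & fused$time > 15
  expect_gt(sum(ok), 10)
  expect_lt(mean(abs(fused$value[ok] - 40)), 2)
  # first estimate appears at the 10 s window end
  expect_equal(min(fused$time), 10)
  # all reported values in range or invalid
  for (ch in ce) {
    v <- ch$value[ch$valid]
    expect_true(all(v >= 18 & v <= 120))
  }
})

test_that("fusion respects single-source and consensus cases", {
  times <- 1:20
  mk <- function(value, sqi) data.frame(time = times, value = value,
                                        sqi = sqi, valid = sqi > 0)
  est <- c(list(mk(50, 1)), replicate(11, mk(NA, 0), simplify = FALSE))
  f1 <- fuse_rr(est)
  expect_equal(f1$value[f1$valid], rep(50, sum(f1$valid)))
  est2 <- replicate(12, mk(60, 0.8), simplify = FALSE)
  f2 <- fuse_rr(est2)
  expect_true(all(abs(f2$value[f2$valid] - 60) < 1e-9))
  est3 <- replicate(3, mk(NA, 0), simplify = FALSE)
  f3 <- fuse_rr(est3)
  expect_false(any(f3$valid))
})
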