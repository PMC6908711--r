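test_that("beat detection recovers clean pulse trains", {
  fs <- 20
  x <- ppgi_signal(pulse_train(2, 30), fs)
  b <- detect_beats(x)
  expect_lte(abs(nrow(b) - 60), 1)
  expect_equal(mean(diff(b$peak)), 0.5, tolerance = 0.05)
  expect_true(all(diff(b$peak) > 0))
  expect_true(all(b$onset < b$peak))
  expect_equal(nrow(detect_beats(ppgi_signal(numeric(600), fs))), 0)
  # the 150 ms upslope window is three samples at 20 Hz
  expect_equal(ceiling(0.150 * 20), 3)
})

test_that("beat scoring gates and self-similarity behave as specified", {
  fs <- 20
  sig <- ppgi_signal(pulse_train(2, 30), fs)
  beats <- detect_beats(sig)
  scored <- score_beats(beats, sig)
  expect_gt(mean(scored$sqi), 0.9)
  expect_true(all(scored$dtw_score > 0.85))
  # beats during an injected active second get SQI 0
  act <- list(second = 5:9, active = rep(TRUE, 5), threshold = 0.02)
  scored2 <- score_beats(beats, sig, activity = act)
  hit <- floor(scored2$peak) %in% 5:9 | floor(scored2$onset) %in% 5:9
  expect_true(all(scored2$sqi[hit] == 0))
  expect_true(all(scored2$sqi[!hit & scored2$gate_rate] > 0))
  # frequency bound gate: 200 beats/min passes, 333 fails
  fake <- data.frame(onset = c(1.0, 1.25), peak = c(1.1, 1.4),
                     onset_idx = c(21L, 26L), peak_idx = c(23L, 29L),
                     amplitude = c(1, 1))
  s200 <- score_beats(fake, sig)
  expect_true(s200$gate_rate[2])     # 0.3 s interval = 200 beats/min
  fake$peak[2] <- 1.28; fake$peak_idx[2] <- 27L
  s333 <- score_beats(fake, sig)
  expect_false(s333$gate_rate[2])    # 0.18 s = 333 beats/min
  # beats within the margin of a change point are gated out
  chg <- list(times = 10, margin = 1)
  s_chg <- score_beats(beats, sig, changes = chg)
  near <- abs(s_chg$peak - 10) <= 1
  expect_true(all(s_chg$sqi[near] == 0))
})

test_that("beat counting follows the interval convention", {
  # 9 peaks spaced 0.5 s: span 4 s, 8 intervals -> 120 beats/min
  est <- hr_beat_counting(seq(2, 6, by = 0.5), c(1.9, 6.1))
  expect_true(est$valid)
  expect_equal(est$value, 120)
  # 2 peaks 1 s apart -> 60 beats/min, below 90 -> invalid
  est2 <- hr_beat_counting(c(3, 4), c(0, 8))
  expect_false(est2$valid)
  expect_false(hr_beat_counting(c(3), c(0, 8))$valid)
  # periodic train at 150 beats/min is exact
  sig <- ppgi_signal(pulse_train(2.5, 30), 20)
  scored <- score_beats(detect_beats(sig), sig)
  est3 <- hr_beat_counting(scored$peak[scored$sqi > 0], c(10, 18))
  expect_equal(est3$value, 150, tolerance = 1)
})

test_that("FFT estimator finds the in-band spectral peak", {
  fs <- 20
  t8 <- seq(0, 8 - 1 / fs, by = 1 / fs)
  est <- hr_fft(sin(2 * pi * 2.5 * t8), fs)
  expect_equal(est$value, 150, tolerance = 0.3)
  # strong out-of-band component is ignored
  x <- 3 * sin(2 * pi * 1.0 * t8) + 0.5 * sin(2 * pi * 2.0 * t8)
  expect_equal(hr_fft(x, fs)$value, 120, tolerance = 0.3)
  # invalid-fraction rule
  xx <- sin(2 * pi * 2 * t8)
  xx[1:60] <- NA
  expect_false(hr_fft(xx, fs)$valid)
  set.seed(1)
  noise_est <- hr_fft(stats::rnorm(160), fs)
  expect_true(noise_est$value >= 90 && noise_est$value <= 270)
})

test_that("Burg AR fit recovers known poles and frequency response", {
  fs <- 20
  # AR(2) process with resonance at 2 Hz
  r <- 0.98; w <- 2 * pi * 2 / fs
  a <- c(2 * r * cos(w), -r^2)
  set.seed(8)
  x <- as.numeric(stats::arima.sim(list(ar = a), 400, sd = 0.1))
  m <- fit_ar(x, 2, fs)
  dom <- neovitals:::ar_dominant_pole(m, c(0.5, 9))
  expect_equal(dom$freq, 2.0, tolerance = 0.05)
  # sinusoid gives a near-unit-circle pole
  t8 <- seq(0, 8, by = 1 / fs)
  m2 <- fit_ar(sin(2 * pi * 3 * t8) + stats::rnorm(161, 0, 0.01), 8, fs)
  d2 <- neovitals:::ar_dominant_pole(m2, c(1.5, 4.5))
  expect_gt(d2$mag, 0.95)
  expect_equal(length(m2$a), 8)
  expect_error(fit_ar(rep(1, 100), 8, fs), "constant")
  expect_error(fit_ar(stats::rnorm(10), 8, fs), "short")
})

test_that("AR dominant pole estimator matches the periodogram on tones", {
  fs <- 20
  t8 <- seq(0, 8 - 1 / fs, by = 1 / fs)
  set.seed(12)
  est <- hr_ar_dominant_pole(sin(2 * pi * 3 * t8) + rnorm(160, 0, 0.05), fs)
  expect_true(est$valid)
  expect_equal(est$value, 180, tolerance = 1)
  # no in-band content: weak in-band pole -> invalid
  set.seed(13)
  low <- 4 * sin(2 * pi * 1.0 * t8) + rnorm(160, 0, 0.02)
  est_low <- hr_ar_dominant_pole(low, fs)
  expect_false(est_low$valid)
  # agreement with the FFT across the band
  for (f0 in seq(1.6, 4.4, length.out = 15)) {
    set.seed(round(100 * f0))
    x <- sin(2 * pi * f0 * t8) + rnorm(160, 0, 0.05)
    e_ar <- hr_ar_dominant_pole(x, fs)
    e_fft <- hr_fft(x, fs)
    expect_true(e_ar$valid, label = sprintf("ar valid at %.2f Hz", f0))
    expect_lt(abs(e_ar$value - e_fft$value), 3)
  }
})

test_that("AR best-model selection agrees on clean tones and falls back on noise", {
  fs <- 20
  t8 <- seq(0, 8 - 1 / fs, by = 1 / fs)
  set.seed(21)
  est <- hr_ar_best_model(sin(2 * pi * 2.2 * t8) + rnorm(160, 0, 0.02), fs)
  expect_true(est$valid)
  expect_false(est$fallback)
  expect_equal(est$value, 132, tolerance = 1)
  # out-of-band tone: no agreeing in-band candidate -> fallback flag
  set.seed(22)
  noise <- 5 * sin(2 * pi * 0.7 * t8) + rnorm(160, 0, 1)
  est_n <- hr_ar_best_model(noise, fs)
  expect_true(est_n$fallback)
  # reproducible bit-exact on fixed input
  x2 <- sin(2 * pi * 2.0 * t8) + 0.8 * sin(2 * pi * 2.1 * t8)
  e1 <- hr_ar_best_model(x2, fs)
  e2 <- hr_ar_best_model(x2, fs)
  expect_identical(e1, e2)
  expect_true(e1$value > 115 && e1$value < 131)
})

test_that("window SQI is the mean beat SQI and estimators stay in range", {
  beats <- data.frame(peak = c(1, 2, 3, 4), sqi = c(1, 0, 0.5, 0.5))
  expect_equal(window_sqi(beats, c(0, 8)), 0.5)
  expect_equal(window_sqi(beats[0, ], c(0, 8)), 0)
  expect_equal(window_sqi(data.frame(peak = 1:2, sqi = c(1, 1)), c(0, 8)), 1)
  # every estimator returns in-range values or an invalid flag
  fs <- 20
  set.seed(30)
  for (k in 1:10) {
    x <- stats::rnorm(160)
    for (est in list(hr_fft(x, fs), hr_ar_dominant_pole(x, fs),
                     hr_ar_best_model(x, fs))) {
      if (est$valid) expect_true(est$value >= 90 && est$value <= 270)
    }
  }
})

test_that("Kalman smoother tracks, holds through gaps, and de-noises", {
  ks <- kalman_smooth(rep(140, 60), rep(1, 60))
  expect_lt(abs(ks$value[15] - 140), 0.1)
  # sqi = 0 gap: prediction only, variance grows, value held
  v <- c(rep(140, 60), rep(NA, 10))
  s <- c(rep(1, 60), rep(0, 10))
  kg <- kalman_smooth(v, s)
  expect_equal(kg$value[70], kg$value[60], tolerance = 0.5)
  expect_gt(kg$variance[70], kg$variance[60])
  expect_false(any(kg$used[61:70]))
  # variance reduction on noisy input
  set.seed(9)
  noisy <- 140 + stats::rnorm(240, 0, 5)
  kn <- kalman_smooth(noisy, rep(1, 240))
  expect_lt(stats::var(kn$value[20:240] - 140), stats::var(noisy - 140))
  # output clipped to range
  kc <- kalman_smooth(rep(300, 10), rep(1, 10))
  expect_true(all(kc$value <= 270))
})
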