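# Shared builders for synthetic inputs used across the test files.

# Small quiet scene: constant rates, no disturbances.
quiet_scene <- function(duration = 30, hr = 120, rr = 60, noise_sd = 0,
                        flicker_sd = 0, seed = 3, ...) {
  generate_scene(scene_config(
    duration = duration, frame_rate = 20, frame_size = c(60, 80),
    hr_schedule = hr, rr_schedule = rr,
    noise_sd = noise_sd, flicker_sd = flicker_sd, seed = seed, ...))
}

# Synthetic pulse train: fundamental plus the 0.3-amplitude first harmonic.
pulse_train <- function(f, duration = 30, fs = 20) {
  t <- seq(0, duration - 1 / fs, by = 1 / fs)
  sin(2 * pi * f * t) + 0.3 * sin(4 * pi * f * t)
}

# Independent periodogram oracle: argmax of the zero-padded FFT power.
periodogram_peak <- function(x, fs, fmin, fmax, nfft = 8192) {
  x <- x[is.finite(x)] - mean(x[is.finite(x)])
  X <- Mod(stats::fft(c(x, numeric(nfft - length(x)))))^2
  f <- (seq_len(nfft) - 1) * fs / nfft
  keep <- f >= fmin & f <= fmax
  f[keep][which.max(X[keep])]
}

# Simple permutation test for a difference in means (one-sided: mean(a) <
# mean(b)).
perm_test_less <- function(a, b, n_perm = 2000, seed = 1) {
  obs <- mean(a) - mean(b)
  pool <- c(a, b)
  na <- length(a)
  set.seed(seed)
  stat <- replicate(n_perm, {
    idx <- sample(length(pool), na)
    mean(pool[idx]) - mean(pool[-idx])
  })
  mean(stat <= obs)
}
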