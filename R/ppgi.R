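# PPGi extraction and the cardiac pre-processing chain.

#' Construct a uniformly-sampled scalar signal
#'
#' Light container used for PPGi and respiratory channel signals: sample
#' values, sampling rate, start time and a per-sample validity flag.
#'
#' @param x Numeric samples (may contain `NA` where invalid).
#' @param fs Sampling rate in Hz.
#' @param t0 Time of the first sample in seconds.
#' @param valid Logical validity flags; defaults to `is.finite(x)`.
#' @param channel Optional source tag.
#' @return An object of class `ppgi_signal`.
#' @export
ppgi_signal <- function(x, fs, t0 = 0, valid = NULL, channel = NULL) {
  if (is.null(valid)) valid <- is.finite(x)
  stopifnot(length(valid) == length(x), fs > 0)
  structure(list(x = as.numeric(x), fs = fs, t0 = t0,
                 valid = as.logical(valid), channel = channel),
            class = "ppgi_signal")
}

#' @export
print.ppgi_signal <- function(x, ...) {
  cat(sprintf("<ppgi_signal> %d samples @ %g Hz (%.1f s), %.1f%% valid%s\n",
              length(x$x), x$fs, length(x$x) / x$fs,
              100 * mean(x$valid),
              if (is.null(x$channel)) "" else paste0(", ", x$channel)))
  invisible(x)
}

#' Sample times of a signal
#' @param sig A [ppgi_signal()].
#' @return Numeric vector of sample times in seconds.
#' @export
signal_times <- function(sig) sig$t0 + (seq_along(sig$x) - 1) / sig$fs

resolve_masks <- function(masks, n) {
  if (is.function(masks)) return(masks)
  if (is.list(masks)) {
    stopifnot(length(masks) == n)
    return(function(i) masks[[i]])
  }
  stop("masks must be a function(i) or a list of per-frame masks")
}

#' Extract a raw PPGi signal from frames and skin masks
#'
#' The raw PPGi value for a frame is the spatial mean of the chosen colour
#' plane over the skin pixels: `sum(C[i,j] * S[i,j]) / N_skin`. Frames with an
#' empty mask yield an invalid sample (`NA`); no value is invented.
#'
#' @param frames A `frame_stream` (see [generate_scene()]) or a list of
#'   rows x cols x 3 arrays.
#' @param masks A `function(i)` returning the binary skin mask for frame `i`,
#'   or a list of masks (one per frame).
#' @param channel One of `"red"`, `"green"`, `"blue"`.
#' @return A [ppgi_signal()] sampled at the frame rate.
#' @export
extract_ppgi <- function(frames, masks, channel = "green") {
  k <- match(match.arg(channel, c("red", "green", "blue")),
             c("red", "green", "blue"))
  if (inherits(frames, "frame_stream")) {
    n <- frames$n
    get_frame <- frames$get_frame
    fs <- frames$frame_rate
    t0 <- frames$timestamps[1]
  } else {
    n <- length(frames)
    get_frame <- function(i) frames[[i]]
    fs <- attr(frames, "frame_rate") %||% 20
    t0 <- 0
  }
  mask_fun <- resolve_masks(masks, n)
  x <- vapply(seq_len(n), function(i) {
    m <- mask_fun(i)
    fr <- get_frame(i)
    if (!identical(dim(m), dim(fr)[1:2]))
      stop("mask and frame dimensions differ for frame ", i)
    ns <- sum(m)
    if (ns == 0) return(NA_real_)
    sum(fr[, , k][m]) / ns
  }, 0)
  ppgi_signal(x, fs, t0 = t0, channel = channel)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# ---- FIR cascade ----------------------------------------------------------

fir_taps <- function(order, fc, fs, type) {
  signal::fir1(order, fc / (fs / 2), type = type)
}

#' Magnitude frequency response of an FIR cascade
#'
#' @param taps_list List of FIR coefficient vectors applied in cascade.
#' @param f Frequencies (Hz) at which to evaluate.
#' @param fs Sampling rate in Hz.
#' @return Magnitude gain at each frequency.
#' @export
fir_cascade_response <- function(taps_list, f, fs) {
  out <- rep(1, length(f))
  for (b in taps_list) {
    H <- vapply(f, function(ff)
      abs(sum(b * exp(-1i * 2 * pi * ff * (seq_along(b) - 1) / fs))), 0)
    out <- out * H
  }
  out
}

#' Taps of the cardiac band-pass cascade
#'
#' A 40th-order low-pass FIR at 4.5 Hz followed by a 60th-order high-pass FIR
#' at 1.5 Hz (Hamming windowed-sinc design), passing the 90-270 beats/min
#' cardiac band at the nominal 20 Hz frame rate.
#'
#' @param fs Sampling rate in Hz.
#' @return List of two coefficient vectors (low-pass, high-pass).
#' @export
cardiac_filter_taps <- function(fs = 20) {
  list(lp = fir_taps(40, 4.5, fs, "low"), hp = fir_taps(60, 1.5, fs, "high"))
}

#' Taps of the respiratory band-pass cascade
#'
#' A 100th-order high-pass FIR at 0.3 Hz followed by an 80th-order low-pass
#' FIR at 2.0 Hz (Hamming design), spanning 18-120 breaths/min.
#'
#' @inheritParams cardiac_filter_taps
#' @return List of two coefficient vectors (high-pass, low-pass).
#' @export
respiratory_filter_taps <- function(fs = 20) {
  list(hp = fir_taps(100, 0.3, fs, "high"), lp = fir_taps(80, 2.0, fs, "low"))
}

# Zero-phase-aligned FIR convolution: full linear convolution trimmed by the
# (order/2) group delay of the symmetric taps.
apply_fir_aligned <- function(x, b) {
  n <- length(x)
  d <- (length(b) - 1) / 2
  y <- stats::convolve(x, rev(b), type = "open")
  y[(d + 1):(d + n)]
}

remove_trend <- function(x) {
  t <- seq_along(x)
  stats::residuals(stats::lm.fit(cbind(1, t), x))
}

# Shared engine for the two cascades. Gaps up to max_bridge seconds are
# bridged by linear interpolation before filtering; longer gaps split the
# signal into independently-filtered segments so filter ringing does not
# leak across absences. Samples in unbridged gaps and segments shorter than
# the cascade remain invalid.
filter_with_cascade <- function(sig, taps, max_bridge = 0.5) {
  stopifnot(inherits(sig, "ppgi_signal"))
  total_len <- sum(vapply(taps, length, 0L))
  if (length(sig$x) < total_len)
    stop("signal shorter than the total filter length (",
         total_len, " samples)")
  x <- sig$x
  x[!sig$valid] <- NA
  maxgap <- max(1L, floor(max_bridge * sig$fs))
  xb <- zoo::na.approx(x, na.rm = FALSE, maxgap = maxgap)
  out <- rep(NA_real_, length(x))
  ok <- is.finite(xb)
  runs <- true_runs(ok)
  for (r in seq_len(nrow(runs))) {
    idx <- runs$start[r]:runs$end[r]
    if (length(idx) < total_len) next
    seg <- remove_trend(xb[idx])
    for (b in taps) seg <- apply_fir_aligned(seg, b)
    out[idx] <- seg
  }
  valid <- is.finite(out)   # bridged short gaps become usable samples
  out[!valid] <- NA
  ppgi_signal(out, sig$fs, t0 = sig$t0, valid = valid, channel = sig$channel)
}

#' Band-pass filter a PPGi signal to the cardiac band
#'
#' Detrends the signal (linear trend removal) and applies the
#' [cardiac_filter_taps()] cascade with group-delay compensation so the
#' output stays time-aligned with the input. Invalid samples propagate;
#' gaps no longer than 0.5 s are bridged by linear interpolation, longer
#' gaps split the signal into independently-filtered segments.
#'
#' @param sig A raw [ppgi_signal()].
#' @return A filtered [ppgi_signal()].
#' @export
filter_cardiac <- function(sig) {
  filter_with_cascade(sig, cardiac_filter_taps(sig$fs))
}

#' Band-pass filter a signal to the respiratory band
#'
#' As [filter_cardiac()] but with the [respiratory_filter_taps()] cascade
#' (0.3-2.0 Hz, i.e. 18-120 breaths/min).
#'
#' @param sig A raw [ppgi_signal()].
#' @return A filtered [ppgi_signal()].
#' @export
filter_respiratory <- function(sig) {
  filter_with_cascade(sig, respiratory_filter_taps(sig$fs))
}

# ---- activity index -------------------------------------------------------

#' Subject activity index from mask changes
#'
#' Per-frame activity is the symmetric-difference fraction of consecutive
#' skin masks, `|S_t xor S_{t-1}| / max(|S_t|, |S_{t-1}|, 1)`; the per-second
#' value is its mean over each second and a second is flagged active when the
#' smoothed value exceeds `threshold`.
#'
#' @param masks `function(i)` or list of per-frame binary masks.
#' @param n_frames Number of frames (required when `masks` is a function).
#' @param frame_rate Frames per second.
#' @param threshold Active-second threshold on the per-second mean.
#' @return List with `frame_activity`, `second` (0-based second index),
#'   `second_activity`, `active` and `threshold`.
#' @export
activity_index <- function(masks, n_frames = NULL, frame_rate = 20,
                           threshold = 0.02) {
  if (is.list(masks)) n_frames <- length(masks)
  stopifnot(!is.null(n_frames), n_frames >= 2)
  mask_fun <- resolve_masks(masks, n_frames)
  act <- numeric(n_frames)
  prev <- mask_fun(1)
  np <- sum(prev)
  for (i in 2:n_frames) {
    cur <- mask_fun(i)
    ncur <- sum(cur)
    act[i] <- sum(xor(cur, prev)) / max(ncur, np, 1)
    prev <- cur
    np <- ncur
  }
  sec_of <- floor((seq_len(n_frames) - 1) / frame_rate)
  second_activity <- tapply(act, sec_of, mean)
  second <- as.integer(names(second_activity))
  list(frame_activity = act,
       second = second,
       second_activity = as.numeric(second_activity),
       active = as.numeric(second_activity) > threshold,
       threshold = threshold)
}

# ---- Bayesian change-point detection --------------------------------------

#' Detect step changes in a signal
#'
#' Bayesian online change-point detection with a constant hazard and a
#' Normal-Gamma observation model, run on the robustly-standardised signal.
#' A change point is reported where the maximum-a-posteriori run length
#' collapses. Samples within `margin` seconds of a change point should be
#' treated as invalid by callers (sudden lighting changes corrupt the pulse
#' waveform around the step).
#'
#' @param sig A [ppgi_signal()] (raw, before cardiac filtering) or a numeric
#'   vector.
#' @param hazard Constant change-point hazard per sample.
#' @param margin Exclusion margin in seconds around each change point.
#' @param max_run Run-length truncation for the posterior recursion.
#' @return List with `indices` (sample indices of detected changes), `times`
#'   (seconds) and `margin`.
#' @export
detect_step_changes <- function(sig, hazard = 1 / 300, margin = 1,
                                max_run = 600) {
  if (inherits(sig, "ppgi_signal")) {
    x <- sig$x
    fs <- sig$fs
    t0 <- sig$t0
  } else {
    x <- as.numeric(sig)
    fs <- 20
    t0 <- 0
  }
  x <- x[seq_along(x)]
  finite <- is.finite(x)
  if (sum(finite) < 10)
    return(list(indices = integer(0), times = numeric(0), margin = margin))
  xi <- x
  xi[!finite] <- stats::median(x[finite])
  s <- stats::mad(xi)
  if (s == 0) s <- stats::sd(xi)
  if (!is.finite(s) || s == 0) s <- 1
  z <- (xi - stats::median(xi)) / s

  n <- length(z)
  # Normal-Gamma prior; predictive is Student-t
  mu0 <- 0; kappa0 <- 1; alpha0 <- 1; beta0 <- 1
  mu <- mu0; kappa <- kappa0; alpha <- alpha0; beta <- beta0
  r_prob <- 1
  rl <- 0L   # run-length label of each posterior component
  map_run <- integer(n)
  for (t in seq_len(n)) {
    df <- 2 * alpha
    scale <- sqrt(beta * (kappa + 1) / (alpha * kappa))
    pred <- stats::dt((z[t] - mu) / scale, df) / scale
    pred <- pmax(pred, 1e-300)
    growth <- r_prob * pred * (1 - hazard)
    cp <- sum(r_prob * pred * hazard)
    r_prob <- c(cp, growth)
    r_prob <- r_prob / sum(r_prob)
    rl <- c(0L, rl + 1L)
    # posterior parameter update (beta uses the pre-update mean)
    beta <- c(beta0, beta + kappa * (z[t] - mu)^2 / (2 * (kappa + 1)))
    mu <- c(mu0, (kappa * mu + z[t]) / (kappa + 1))
    kappa <- c(kappa0, kappa + 1)
    alpha <- c(alpha0, alpha + 0.5)
    # prune negligible-probability run lengths (keeps the recursion O(1)
    # per step in practice); always keep the newest and the most probable
    keep <- r_prob > 1e-8
    keep[1L] <- TRUE
    keep[which.max(r_prob)] <- TRUE
    if (length(r_prob) > max_run) {
      ord <- order(r_prob, decreasing = TRUE)[seq_len(max_run)]
      keep <- keep & seq_along(r_prob) %in% ord
    }
    r_prob <- r_prob[keep] / sum(r_prob[keep])
    rl <- rl[keep]; mu <- mu[keep]; kappa <- kappa[keep]
    alpha <- alpha[keep]; beta <- beta[keep]
    map_run[t] <- rl[which.max(r_prob)]
  }
  drops <- which(diff(map_run) < -20 & map_run[-1] <= 3) + 1L
  # collapse detections within one margin of each other
  if (length(drops) > 1) {
    keep <- c(TRUE, diff(drops) > margin * fs)
    drops <- drops[keep]
  }
  idx <- as.integer(drops - map_run[drops])  # first sample of the new regime
  list(indices = idx, times = t0 + (idx - 1L) / fs, margin = margin)
}
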