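# Beat detection, beat-by-beat quality assessment, heart-rate estimators
# and SQI-weighted Kalman smoothing.

# Slope-sum event detector shared by the cardiac (150 ms upslope) and
# respiratory (300 ms upslope) chains. Onsets are located at the start of
# the supra-threshold upslope run; the peak is the maximum of the signal
# within the following search window. The threshold is initialised from the
# first 2 s of the transform and tracks an exponential moving average of
# detected slope-sum amplitudes, decaying slowly while idle so detection
# recovers after quiet spells.
slope_sum_detect <- function(x, fs, upslope_s, refractory_s,
                             search_s = 2.5 * upslope_s + 0.25,
                             thresh_frac = 0.6) {
  n <- length(x)
  empty <- data.frame(onset = numeric(0), peak = numeric(0),
                      onset_idx = integer(0), peak_idx = integer(0),
                      amplitude = numeric(0))
  if (n < 2 * fs) return(empty)
  w <- ceiling(upslope_s * fs)
  ssf <- slope_sum(x, w)
  init <- max(ssf[seq_len(min(n, ceiling(2 * fs)))])
  if (init <= 0) return(empty)
  M <- init                      # running slope-sum amplitude estimate
  decay <- 0.5^(1 / (5 * fs))    # threshold halves over 5 idle seconds
  refr <- max(1L, floor(refractory_s * fs))
  search <- ceiling(search_s * fs)
  onsets <- integer(0); peaks <- integer(0)
  i <- w + 1L
  last_fire <- -Inf
  armed <- TRUE   # re-armed once the slope sum falls back below thr/2
  while (i <= n) {
    thr <- thresh_frac * M
    if (!armed && ssf[i] < thr / 2) armed <- TRUE
    if (armed && ssf[i] > thr && i - last_fire > refr) {
      onset <- max(1L, i - w)
      j_end <- min(n, i + search)
      # slope-sum maximum within the event updates the running amplitude
      run_end <- i
      while (run_end < j_end && ssf[run_end + 1L] > thr) run_end <- run_end + 1L
      A <- max(ssf[i:run_end])
      M <- 0.8 * M + 0.2 * A
      # the pulse crest sits at the end of the supra-threshold upslope run
      p_end <- min(n, run_end + w)
      peak <- onset + which.max(x[onset:p_end]) - 1L
      if (peak > onset &&
          (length(peaks) == 0L || peak > peaks[length(peaks)])) {
        onsets <- c(onsets, onset)
        peaks <- c(peaks, peak)
        last_fire <- i
        armed <- FALSE
      }
      i <- max(i, run_end) + 1L
    } else {
      M <- M * decay
      i <- i + 1L
    }
  }
  keep <- !duplicated(peaks)
  onsets <- onsets[keep]; peaks <- peaks[keep]
  data.frame(onset = (onsets - 1) / fs, peak = (peaks - 1) / fs,
             onset_idx = onsets, peak_idx = peaks,
             amplitude = x[peaks] - x[onsets])
}

#' Detect cardiac pulses in a filtered PPGi signal
#'
#' Slope-sum transform with a 150 ms upslope window (three samples at the
#' nominal 20 Hz frame rate) and an adaptive threshold initialised from the
#' first two seconds, with a 60/270 s refractory period between beats.
#' Onsets mark the start of the pulse upslope; the peak is the local signal
#' maximum that follows.
#'
#' @param filtered A cardiac-filtered [ppgi_signal()].
#' @return Data frame with one row per beat: `onset`, `peak` (seconds),
#'   `onset_idx`, `peak_idx`, `amplitude` (peak minus onset value).
#' @export
detect_beats <- function(filtered) {
  stopifnot(inherits(filtered, "ppgi_signal"))
  x <- filtered$x
  x[!filtered$valid] <- 0
  x[!is.finite(x)] <- 0
  ev <- slope_sum_detect(x, filtered$fs, upslope_s = 0.150,
                         refractory_s = 60 / 270)
  ev$onset <- ev$onset + filtered$t0
  ev$peak <- ev$peak + filtered$t0
  ev
}

# Resample a beat to n samples and normalise amplitude to [0, 1].
normalise_shape <- function(seg, n = 25) {
  seg <- seg[is.finite(seg)]
  if (length(seg) < 3) return(NULL)
  s <- resample_to(seg, n)
  rng <- diff(range(s))
  if (rng <= 0) return(NULL)
  (s - min(s)) / rng
}

# Multi-scale DTW similarity between a beat shape and a template: the
# length-normalised DTW distance averaged over full and half resolution,
# mapped through exp(-d / tau).
dtw_similarity <- function(shape, template, tau = 0.5) {
  d1 <- dtw_distance(shape, template)
  half <- function(s) resample_to(s, ceiling(length(s) / 2))
  d2 <- dtw_distance(half(shape), half(template))
  exp(-mean(c(d1, d2)) / tau)
}

#' Score detected beats
#'
#' Applies the beat-level quality gates and the multi-scale dynamic time
#' warping (DTW) similarity score. Gates: beats overlapping an active second
#' (subject motion) fail; beats within the exclusion margin of a detected
#' step change fail; an instantaneous rate from the preceding inter-beat
#' interval outside `rate_range` fails; three or more consecutive samples
#' pinned at the beat extremum (clipping) fail; a beat amplitude outside
#' `[0.25, 4]` times the running median of the last 15 accepted amplitudes
#' fails. The DTW score compares each beat, resampled to 25 samples and
#' amplitude-normalised, against an exponential-moving-average template of
#' accepted beats at two scales. The combined SQI is the DTW score when all
#' gates pass and 0 otherwise.
#'
#' @param beats Data frame from [detect_beats()].
#' @param filtered The cardiac-filtered [ppgi_signal()] the beats came from.
#' @param activity Optional [activity_index()] result.
#' @param changes Optional [detect_step_changes()] result.
#' @param rate_range Physiological rate bounds in events/min.
#' @param tau DTW-to-SQI scale parameter.
#' @param template_alpha Exponential moving-average weight for template
#'   updates.
#' @param template_reset_s Template is restarted after this many seconds
#'   without an accepted beat.
#' @return `beats` with gate columns (`gate_activity`, `gate_change`,
#'   `gate_rate`, `gate_clip`, `gate_amplitude`), `dtw_score` and the
#'   combined `sqi`.
#' @export
score_beats <- function(beats, filtered, activity = NULL, changes = NULL,
                        rate_range = c(90, 270), tau = 0.5,
                        template_alpha = 0.1, template_reset_s = 10) {
  nb <- nrow(beats)
  cols <- c("gate_activity", "gate_change", "gate_rate", "gate_clip",
            "gate_amplitude")
  if (nb == 0) {
    for (cc in cols) beats[[cc]] <- logical(0)
    beats$dtw_score <- numeric(0)
    beats$sqi <- numeric(0)
    return(beats)
  }
  x <- filtered$x
  fs <- filtered$fs
  active_secs <- if (is.null(activity)) integer(0) else
    activity$second[activity$active]
  change_times <- if (is.null(changes)) numeric(0) else changes$times
  margin <- if (is.null(changes)) 1 else changes$margin

  g_act <- g_chg <- g_rate <- g_clip <- g_amp <- rep(TRUE, nb)
  dtw_score <- rep(NA_real_, nb)
  accepted_amps <- numeric(0)
  template <- NULL
  last_accept_t <- -Inf

  for (b in seq_len(nb)) {
    secs <- floor(beats$onset[b]):floor(beats$peak[b])
    g_act[b] <- !any(secs %in% active_secs)
    if (length(change_times))
      g_chg[b] <- all(abs(beats$peak[b] - change_times) > margin)
    if (b > 1) {
      ibi <- beats$peak[b] - beats$peak[b - 1]
      rate <- 60 / ibi
      g_rate[b] <- rate >= rate_range[1] && rate <= rate_range[2]
    }
    seg <- x[beats$onset_idx[b]:min(beats$peak_idx[b] + ceiling(0.2 * fs),
                                    length(x))]
    seg <- seg[is.finite(seg)]
    if (length(seg) >= 3) {
      r <- rle(seg)
      at_ext <- r$values %in% range(seg)
      g_clip[b] <- !any(r$lengths[at_ext] >= 3)
    }
    if (length(accepted_amps) >= 5) {
      med <- stats::median(utils::tail(accepted_amps, 15))
      g_amp[b] <- beats$amplitude[b] >= 0.25 * med &&
        beats$amplitude[b] <= 4 * med
    }
    gates_ok <- g_act[b] && g_chg[b] && g_rate[b] && g_clip[b] && g_amp[b]

    end_idx <- if (b < nb) beats$onset_idx[b + 1] else
      min(beats$onset_idx[b] + ceiling(0.6 * fs), length(x))
    shape <- normalise_shape(x[beats$onset_idx[b]:end_idx])
    if (!is.null(shape)) {
      if (!is.null(template) &&
          beats$peak[b] - last_accept_t > template_reset_s)
        template <- NULL
      if (is.null(template)) {
        dtw_score[b] <- 1   # first beat seeds the template
        if (gates_ok) template <- shape
      } else {
        dtw_score[b] <- dtw_similarity(shape, template, tau)
        if (gates_ok)
          template <- (1 - template_alpha) * template + template_alpha * shape
      }
      if (gates_ok) {
        accepted_amps <- c(accepted_amps, beats$amplitude[b])
        last_accept_t <- beats$peak[b]
      }
    } else dtw_score[b] <- 0
  }
  beats$gate_activity <- g_act
  beats$gate_change <- g_chg
  beats$gate_rate <- g_rate
  beats$gate_clip <- g_clip
  beats$gate_amplitude <- g_amp
  all_gates <- g_act & g_chg & g_rate & g_clip & g_amp
  beats$dtw_score <- dtw_score
  beats$sqi <- ifelse(all_gates, dtw_score, 0)
  beats
}

invalid_estimate <- function(method) {
  list(value = NA_real_, valid = FALSE, method = method, fallback = FALSE)
}

check_range <- function(est, range) {
  if (est$valid && (est$value < range[1] || est$value > range[2])) {
    est$valid <- FALSE
  }
  est
}

#' Heart rate by beat counting
#'
#' Counts inter-peak intervals over a window expanded to the peaks of the
#' first and last beats: `HR = (n_peaks - 1) * 60 / span`, exact on a
#' periodic train. Fewer than two usable peaks, or a value outside
#' `rate_range`, gives an invalid estimate.
#'
#' @param peak_times Peak times (seconds) of usable beats in and adjacent to
#'   the window.
#' @param window `c(start, end)` of the nominal window in seconds.
#' @param rate_range Valid output range in events/min.
#' @param max_gap Largest peak-to-window-edge gap (seconds) for a peak just
#'   outside the window to be pulled in when expanding; defaults to the
#'   longest physiological interval, `60 / rate_range[1]`.
#' @return List with `value`, `valid`, `method`, `fallback`.
#' @export
hr_beat_counting <- function(peak_times, window, rate_range = c(90, 270),
                             max_gap = 60 / rate_range[1]) {
  method <- "count"
  inside <- peak_times >= window[1] & peak_times <= window[2]
  sel <- peak_times[inside]
  before <- peak_times[peak_times < window[1]]
  after <- peak_times[peak_times > window[2]]
  if (length(before) && window[1] - max(before) <= max_gap)
    sel <- c(max(before), sel)
  if (length(after) && min(after) - window[2] <= max_gap)
    sel <- c(sel, min(after))
  if (length(sel) < 2) return(invalid_estimate(method))
  span <- sel[length(sel)] - sel[1]
  if (span <= 0) return(invalid_estimate(method))
  check_range(list(value = (length(sel) - 1) * 60 / span, valid = TRUE,
                   method = method, fallback = FALSE), rate_range)
}

#' Heart rate by FFT spectral peak
#'
#' Zero-pads the window to `nfft` points and returns 60 times the frequency
#' of the largest periodogram power inside the cardiac band.
#'
#' @param x Filtered samples of one window (NA where invalid).
#' @param fs Sampling rate in Hz.
#' @param band Frequency band searched, Hz.
#' @param nfft FFT length after zero padding.
#' @param max_invalid_frac Windows with a larger invalid fraction return an
#'   invalid estimate.
#' @return List with `value`, `valid`, `method`, `fallback`.
#' @export
hr_fft <- function(x, fs, band = c(1.5, 4.5), nfft = 4096,
                   max_invalid_frac = 0.25) {
  method <- "fft"
  bad <- !is.finite(x)
  if (mean(bad) > max_invalid_frac) return(invalid_estimate(method))
  xi <- x
  xi[bad] <- mean(x[!bad])
  f <- dominant_frequency(xi, fs, band[1], band[2], nfft)
  if (!is.finite(f)) return(invalid_estimate(method))
  check_range(list(value = 60 * f, valid = TRUE, method = method,
                   fallback = FALSE), 60 * band)
}

#' Fit an autoregressive model by Burg's method
#'
#' @param x Window samples (finite values only are used after mean removal;
#'   constant input is an error).
#' @param p Model order.
#' @param fs Sampling rate in Hz.
#' @return List of class `ar_model` with `order`, `a` (coefficients of the
#'   prediction polynomial), `var` (innovation variance), `poles` (complex),
#'   `pole_freq` (Hz), `pole_mag`, and `S(f)` the model frequency response.
#' @export
fit_ar <- function(x, p, fs) {
  x <- x[is.finite(x)]
  if (length(x) <= 2 * p)
    stop("window too short for AR order ", p)
  if (stats::sd(x) == 0) stop("degenerate (constant) input")
  fit <- stats::ar.burg(x, aic = FALSE, order.max = p, demean = TRUE)
  a <- fit$ar
  sigma2 <- fit$var.pred
  poles <- polyroot(c(-rev(a), 1))
  pole_freq <- Arg(poles) * fs / (2 * pi)
  S <- function(f) {
    vapply(f, function(ff) {
      A <- 1 - sum(a * exp(-1i * 2 * pi * ff * seq_len(p) / fs))
      sigma2 / Mod(A)^2
    }, 0)
  }
  structure(list(order = p, a = a, var = sigma2, poles = poles,
                 pole_freq = pole_freq, pole_mag = Mod(poles),
                 fs = fs, S = S),
            class = "ar_model")
}

ar_dominant_pole <- function(model, band) {
  sel <- model$pole_freq >= band[1] & model$pole_freq <= band[2]
  if (!any(sel)) return(NULL)
  k <- which(sel)[which.max(model$pole_mag[sel])]
  list(freq = model$pole_freq[k], mag = model$pole_mag[k])
}

ar_response_peak <- function(model, band, df = 0.005) {
  f <- seq(band[1], band[2], by = df)
  f[which.max(model$S(f))]
}

#' Heart rate from the dominant pole of a fixed-order AR model
#'
#' Fits an order-8 Burg AR model and selects, among the poles whose angle
#' maps into the cardiac band, the one with the largest magnitude. The
#' estimate is invalid when no in-band pole exists or the dominant in-band
#' pole is weak (magnitude below `min_pole_mag`).
#'
#' @inheritParams hr_fft
#' @param order Model order.
#' @param min_pole_mag Minimum dominant-pole magnitude for a valid estimate.
#' @return List with `value`, `valid`, `method`, `fallback`, `pole_mag`.
#' @export
hr_ar_dominant_pole <- function(x, fs, band = c(1.5, 4.5), order = 8,
                                min_pole_mag = 0.8,
                                max_invalid_frac = 0.25) {
  method <- "ar_pole"
  bad <- !is.finite(x)
  if (mean(bad) > max_invalid_frac) return(invalid_estimate(method))
  xi <- x[!bad]
  if (length(xi) <= 2 * order || stats::sd(xi) == 0)
    return(invalid_estimate(method))
  model <- fit_ar(xi, order, fs)
  dom <- ar_dominant_pole(model, band)
  if (is.null(dom) || dom$mag < min_pole_mag) {
    out <- invalid_estimate(method)
    out$pole_mag <- if (is.null(dom)) NA_real_ else dom$mag
    return(out)
  }
  out <- check_range(list(value = 60 * dom$freq, valid = TRUE,
                          method = method, fallback = FALSE), 60 * band)
  out$pole_mag <- dom$mag
  out
}

#' Heart rate by AR best-model-order selection
#'
#' Fits AR models of order 6 to 12. Orders for which the dominant in-band
#' pole frequency and the peak of the model frequency response agree to
#' within 1 beat/min are candidates; among candidates the model with the
#' largest dominant-pole magnitude wins. With no candidate the estimate
#' falls back to the frequency-response peak of the order-8 model and
#' carries `fallback = TRUE`.
#'
#' @inheritParams hr_fft
#' @param orders Model orders searched.
#' @param agree_tol Pole/response agreement tolerance in beats/min.
#' @param fallback_order Order used for the fallback spectral estimate.
#' @return List with `value`, `valid`, `method`, `fallback`, `order`.
#' @export
hr_ar_best_model <- function(x, fs, band = c(1.5, 4.5), orders = 6:12,
                             agree_tol = 1, fallback_order = 8,
                             max_invalid_frac = 0.25) {
  method <- "ar_best"
  bad <- !is.finite(x)
  if (mean(bad) > max_invalid_frac) return(invalid_estimate(method))
  xi <- x[!bad]
  if (length(xi) <= 2 * max(orders) || stats::sd(xi) == 0)
    return(invalid_estimate(method))
  best <- NULL
  for (p in orders) {
    model <- fit_ar(xi, p, fs)
    dom <- ar_dominant_pole(model, band)
    if (is.null(dom)) next
    f_resp <- ar_response_peak(model, band)
    if (abs(60 * dom$freq - 60 * f_resp) < agree_tol) {
      if (is.null(best) || dom$mag > best$mag)
        best <- list(freq = dom$freq, mag = dom$mag, order = p)
    }
  }
  if (is.null(best)) {
    model <- fit_ar(xi, fallback_order, fs)
    f <- ar_response_peak(model, band)
    out <- check_range(list(value = 60 * f, valid = TRUE, method = method,
                            fallback = TRUE), 60 * band)
    out$order <- fallback_order
    return(out)
  }
  out <- check_range(list(value = 60 * best$freq, valid = TRUE,
                          method = method, fallback = FALSE), 60 * band)
  out$order <- best$order
  out
}

#' Window signal quality
#'
#' Mean of the combined beat SQIs whose peaks fall in the window; 0 when the
#' window contains no beats.
#'
#' @param beats Scored beats from [score_beats()].
#' @param window `c(start, end)` in seconds.
#' @return SQI in `[0, 1]`.
#' @export
window_sqi <- function(beats, window) {
  sel <- beats$peak >= window[1] & beats$peak <= window[2]
  if (!any(sel)) return(0)
  mean(beats$sqi[sel])
}

#' Estimate heart rate on a sliding window
#'
#' Runs the chosen estimators over an 8 s window sliding in 1 s steps (the
#' first estimate appears at 8 s, stamped at the window end) and attaches
#' the window SQI.
#'
#' @param filtered Cardiac-filtered [ppgi_signal()].
#' @param beats Scored beats from [score_beats()].
#' @param methods Subset of `c("count", "fft", "ar_pole", "ar_best")`.
#' @param window_s Window length in seconds.
#' @param rate_range Valid output range in beats/min.
#' @return Data frame with columns `time`, `method`, `value`, `sqi`,
#'   `valid`, `fallback`.
#' @export
estimate_hr <- function(filtered, beats,
                        methods = c("count", "fft", "ar_pole", "ar_best"),
                        window_s = 8, rate_range = c(90, 270)) {
  fs <- filtered$fs
  x <- filtered$x
  x[!filtered$valid] <- NA
  duration <- length(x) / fs
  ends <- seq(window_s, floor(duration), by = 1)
  good_peaks <- beats$peak[beats$sqi > 0]
  rows <- list()
  for (te in ends) {
    win <- c(te - window_s, te)
    idx <- which(signal_times(filtered) > win[1] &
                   signal_times(filtered) <= win[2])
    xs <- x[idx]
    sqi <- window_sqi(beats, win)
    for (m in methods) {
      est <- switch(m,
        count = hr_beat_counting(good_peaks, win, rate_range),
        fft = hr_fft(xs, fs, band = rate_range / 60),
        ar_pole = hr_ar_dominant_pole(xs, fs, band = rate_range / 60),
        ar_best = hr_ar_best_model(xs, fs, band = rate_range / 60))
      rows[[length(rows) + 1L]] <- data.frame(
        time = te, method = m, value = est$value, sqi = sqi,
        valid = est$valid, fallback = isTRUE(est$fallback))
    }
  }
  do.call(rbind, rows)
}

#' SQI-weighted Kalman smoothing of a vital-sign series
#'
#' Scalar random-walk Kalman filter over a 1 Hz estimate series. The
#' measurement variance is inflated by the signal quality
#' (`r / max(sqi, sqi_floor)^2`); measurements with `sqi < missing_below`
#' or an invalid flag are treated as missing (prediction only, growing
#' posterior variance). The posterior mean is clipped to `range`.
#'
#' @param value Measurement series (NA allowed).
#' @param sqi Per-measurement quality in `[0, 1]`.
#' @param valid Logical validity of each measurement.
#' @param q Process variance per step.
#' @param r Base measurement variance.
#' @param sqi_floor Lower bound applied to SQI in the variance inflation.
#' @param missing_below Measurements with SQI below this are ignored.
#' @param range Output clipping range.
#' @return Data frame with `value` (posterior mean), `variance` (posterior
#'   variance) and `used` (whether the measurement was assimilated).
#' @export
kalman_smooth <- function(value, sqi, valid = is.finite(value), q = 4, r = 4,
                          sqi_floor = 0.05, missing_below = 0.3,
                          range = c(90, 270)) {
  n <- length(value)
  stopifnot(length(sqi) == n, length(valid) == n)
  xhat <- rep(NA_real_, n)
  Pout <- rep(NA_real_, n)
  used <- rep(FALSE, n)
  x <- NA_real_
  P <- NA_real_
  for (t in seq_len(n)) {
    use <- valid[t] && is.finite(value[t]) && sqi[t] >= missing_below
    if (is.na(x)) {
      if (use) {
        x <- value[t]
        P <- r / max(sqi[t], sqi_floor)^2
        used[t] <- TRUE
      }
    } else {
      P <- P + q
      if (use) {
        R <- r / max(sqi[t], sqi_floor)^2
        K <- P / (P + R)
        x <- x + K * (value[t] - x)
        P <- (1 - K) * P
        used[t] <- TRUE
      }
    }
    if (!is.na(x)) {
      xhat[t] <- min(max(x, range[1]), range[2])
      Pout[t] <- P
    }
  }
  data.frame(value = xhat, variance = Pout, used = used)
}
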