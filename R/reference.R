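# Gold-standard reference heart rate and respiratory rate from monitor
# waveforms: waveform quality indices, agreement gating and two-method
# respiratory fusion.

# Derivative-threshold QRS detector: adaptive threshold on the positive
# slope, peak refined to the local signal maximum.
detect_r_peaks_deriv <- function(x, fs, refractory_s = 0.2) {
  n <- length(x)
  if (n < fs) return(numeric(0))
  dx <- c(0, diff(x))
  thr <- 0.5 * stats::quantile(dx[dx > 0], 0.995, names = FALSE)
  if (!is.finite(thr) || thr <= 0) return(numeric(0))
  refr <- max(1L, floor(refractory_s * fs))
  cand <- which(dx > thr)
  peaks <- integer(0)
  last <- -Inf
  half <- ceiling(0.05 * fs)
  for (i in cand) {
    if (i - last <= refr) next
    j_end <- min(n, i + half)
    pk <- i + which.max(x[i:j_end]) - 1L
    if (length(peaks) == 0L || pk > peaks[length(peaks)]) {
      peaks <- c(peaks, pk)
      last <- pk
    }
  }
  (peaks - 1) / fs
}

# Slope-sum QRS detector (30 ms upslope at the ECG rate).
detect_r_peaks_ssf <- function(x, fs, refractory_s = 0.2) {
  ev <- slope_sum_detect(x, fs, upslope_s = 0.03, refractory_s = refractory_s,
                         search_s = 0.08)
  ev$peak
}

#' ECG signal quality by detector agreement
#'
#' Runs two independent QRS detectors (slope-sum and derivative-threshold)
#' over the window and scores their agreement: the SQI is the F1 score of
#' one-to-one beat matching within a 150 ms pairing tolerance. Clean ECG
#' gives near-perfect agreement; noise drives the detectors apart.
#'
#' @param x ECG samples of one window (>= 10 s recommended).
#' @param fs Sampling rate in Hz.
#' @param pair_tol_s Beat pairing tolerance in seconds.
#' @return SQI in `[0, 1]`.
#' @export
ecg_sqi <- function(x, fs, pair_tol_s = 0.150) {
  a <- detect_r_peaks_ssf(x, fs)
  b <- detect_r_peaks_deriv(x, fs)
  if (length(a) < 2 && length(b) < 2) return(0)
  match_events_f1(a, b, pair_tol_s)
}

#' PPG signal quality by pulse-template correlation
#'
#' Detects pulses with the slope-sum transform, extracts a fixed-length
#' segment around each pulse peak, and correlates each pulse against the
#' window's average pulse. The SQI is the mean Pearson correlation mapped
#' to `[0, 1]` via `max(0, r)`; fewer than two pulses give 0 (insufficient
#' evidence).
#'
#' @param x PPG samples of one window.
#' @param fs Sampling rate in Hz.
#' @return SQI in `[0, 1]`.
#' @export
ppg_sqi <- function(x, fs) {
  ev <- slope_sum_detect(x, fs, upslope_s = 0.15, refractory_s = 60 / 270)
  if (nrow(ev) < 2) return(0)
  ibi <- stats::median(diff(ev$peak_idx))
  half <- max(2L, floor(0.45 * ibi))
  pulses <- lapply(ev$peak_idx, function(p) {
    i0 <- p - half; i1 <- p + half
    if (i0 < 1 || i1 > length(x)) return(NULL)
    x[i0:i1]
  })
  pulses <- Filter(Negate(is.null), pulses)
  if (length(pulses) < 2) return(0)
  P <- do.call(cbind, pulses)
  avg <- rowMeans(P)
  if (stats::sd(avg) == 0) return(0)
  r <- apply(P, 2, function(p)
    if (stats::sd(p) == 0) 0 else stats::cor(p, avg))
  max(0, mean(r))
}

#' Gold-standard reference heart rate
#'
#' A second is valid when the ECG- and PPG-derived monitor heart rates do
#' not differ by more than 5 beats/min and both waveform SQIs exceed 0.5;
#' the reference value is then the mean of the two measurements.
#'
#' @param hr_ecg,hr_ppg 1 Hz heart-rate numerics (beats/min).
#' @param sqi_ecg,sqi_ppg Per-second waveform SQIs.
#' @param max_diff Maximum allowed |hr_ecg - hr_ppg| (inclusive).
#' @param min_sqi SQI threshold (strict inequality).
#' @return Data frame with `value`, `valid` and the constituent columns.
#' @export
reference_hr <- function(hr_ecg, hr_ppg, sqi_ecg, sqi_ppg,
                         max_diff = 5, min_sqi = 0.5) {
  n <- length(hr_ecg)
  stopifnot(length(hr_ppg) == n, length(sqi_ecg) == n, length(sqi_ppg) == n)
  ok <- is.finite(hr_ecg) & is.finite(hr_ppg) &
    abs(hr_ecg - hr_ppg) <= max_diff & sqi_ecg > min_sqi & sqi_ppg > min_sqi
  data.frame(value = ifelse(ok, (hr_ecg + hr_ppg) / 2, NA_real_),
             valid = ok, hr_ecg = hr_ecg, hr_ppg = hr_ppg,
             sqi_ecg = sqi_ecg, sqi_ppg = sqi_ppg)
}

#' Respiration surrogates from the ECG
#'
#' Derives the three ECG respiration surrogates at the detected R-peaks and
#' resamples each to a uniform 4 Hz grid by cubic spline interpolation:
#' R-peak amplitude (RPA), respiratory sinus arrhythmia (RSA, the
#' instantaneous rate 60/IBI at each beat) and ECG-derived respiration
#' (EDR, the QRS area within +-50 ms of each R-peak).
#'
#' @param ecg List with `x` (samples) and `fs` (Hz), as produced by
#'   [generate_reference_waveforms()].
#' @param r_peaks Optional R-peak times (seconds); detected when missing.
#' @param out_fs Output grid rate in Hz.
#' @return List with `t` (grid times) and `rpa`, `rsa`, `edr` series, or
#'   empty vectors when fewer than 4 beats are found.
#' @export
derive_resp_surrogates <- function(ecg, r_peaks = NULL, out_fs = 4) {
  x <- ecg$x
  fs <- ecg$fs
  if (is.null(r_peaks)) r_peaks <- detect_r_peaks_ssf(x, fs)
  empty <- list(t = numeric(0), rpa = numeric(0), rsa = numeric(0),
                edr = numeric(0))
  if (length(r_peaks) < 4) return(empty)
  idx <- round(r_peaks * fs) + 1L
  idx <- idx[idx >= 1 & idx <= length(x)]
  if (length(idx) < 4) return(empty)
  rpa <- x[idx]
  half <- round(0.05 * fs)
  edr <- vapply(idx, function(i) {
    i0 <- max(1L, i - half); i1 <- min(length(x), i + half)
    sum(x[i0:i1]) / fs
  }, 0)
  bt <- (idx - 1) / fs
  rsa_t <- bt[-1]
  rsa <- 60 / diff(bt)
  tg <- seq(bt[2], bt[length(bt) - 1], by = 1 / out_fs)
  sp <- function(xt, xv) stats::spline(xt, xv, xout = tg, method = "natural")$y
  list(t = tg,
       rpa = sp(bt, rpa),
       rsa = sp(rsa_t, rsa),
       edr = sp(bt, edr))
}

# Per-signal, per-window respiratory estimates for the reference chain:
# counting (slope-sum detector at the surrogate rate) and AR dominant pole,
# both gated by spectral purity.
reference_rr_signal <- function(x, fs, window_s = 20, step_s = 1,
                                band = c(0.3, 2.0), order = 8,
                                purity_gate = 0.5) {
  n <- length(x)
  duration <- n / fs
  if (floor(duration) < window_s)
    return(data.frame(time = numeric(0), count = numeric(0),
                      ar = numeric(0), sqi = numeric(0)))
  ends <- seq(window_s, floor(duration), by = step_s)
  res <- data.frame(time = ends, count = NA_real_, ar = NA_real_, sqi = 0)
  sig <- ppgi_signal(x, fs)
  # light high-pass by subtracting a 5 s running mean (the surrogate grids
  # are too slow for the video-rate FIR cascade)
  w <- max(3L, round(5 * fs))
  base <- as.numeric(stats::filter(x, rep(1 / w, w), sides = 2))
  base <- zoo::na.locf(zoo::na.locf(base, na.rm = FALSE), fromLast = TRUE)
  xf <- x - base
  ev <- slope_sum_detect(xf, fs, upslope_s = 0.3, refractory_s = 0.5)
  for (k in seq_along(ends)) {
    win <- c(ends[k] - window_s, ends[k])
    sel <- which(seq_len(n) / fs > win[1] & seq_len(n) / fs <= win[2])
    xw <- xf[sel]
    pur <- spectral_purity(xw, fs, band[1], band[2])
    if (pur < purity_gate) next
    cnt <- rr_estimate(ev$peak, win)
    if (cnt$valid) res$count[k] <- cnt$value
    md <- tryCatch(fit_ar(xw, order, fs), error = function(e) NULL)
    if (!is.null(md)) {
      dom <- ar_dominant_pole(md, band)
      if (!is.null(dom)) {
        v <- 60 * dom$freq
        if (v >= 18 && v <= 120) res$ar[k] <- v
      }
    }
    res$sqi[k] <- pur
  }
  res
}

#' Gold-standard reference respiratory rate
#'
#' Estimates respiratory rate from four signals (EDR, RSA, RPA and the
#' impedance pneumography waveform resampled to the surrogate grid) by two
#' methods each: breath counting and the dominant pole of an order-8 AR
#' model in the 0.3-2.0 Hz band. Each method's four per-signal series are
#' fused with SQI-weighted Kalman filters; a second is valid when both
#' fused estimates exist and differ by less than 5 breaths/min, the value
#' being their mean.
#'
#' @param surrogates Output of [derive_resp_surrogates()].
#' @param ip List with `x`, `fs` for the impedance pneumography waveform.
#' @param window_s Estimation window in seconds.
#' @param max_diff Strict bound on the two-method difference (breaths/min).
#' @return Data frame with `time`, `value`, `valid`, `rr_count`, `rr_ar`.
#' @export
reference_rr <- function(surrogates, ip, window_s = 20, max_diff = 5) {
  out_fs <- if (length(surrogates$t) > 1)
    1 / diff(surrogates$t[1:2]) else 4
  ip_t <- (seq_along(ip$x) - 1) / ip$fs
  signals <- list()
  if (length(surrogates$t) >= window_s * out_fs) {
    signals$edr <- surrogates$edr
    signals$rsa <- surrogates$rsa
    signals$rpa <- surrogates$rpa
    tg <- surrogates$t
  } else {
    tg <- seq(0, max(ip_t), by = 1 / out_fs)
  }
  signals$ip <- stats::spline(ip_t, ip$x, xout = tg, method = "natural")$y

  per_sig <- lapply(signals, function(x)
    reference_rr_signal(x, out_fs, window_s = window_s))
  times <- per_sig[[1]]$time
  mk <- function(col) lapply(per_sig, function(d)
    data.frame(time = d$time, value = d[[col]], sqi = d$sqi,
               valid = is.finite(d[[col]])))
  fused_count <- fuse_rr(mk("count"), range = c(18, 120))
  fused_ar <- fuse_rr(mk("ar"), range = c(18, 120))
  ok <- fused_count$valid & fused_ar$valid &
    abs(fused_count$value - fused_ar$value) < max_diff
  data.frame(time = times,
             value = ifelse(ok, (fused_count$value + fused_ar$value) / 2,
                            NA_real_),
             valid = ok,
             rr_count = fused_count$value, rr_ar = fused_ar$value)
}

#' Build per-second reference vitals from monitor waveforms
#'
#' Computes sliding-window ECG and PPG SQIs (10 s windows aligned to each
#' second), applies the heart-rate agreement rule to the 1 Hz monitor
#' numerics, and constructs the reference respiratory rate from the ECG
#' surrogates and the impedance pneumography waveform.
#'
#' @param waveforms A [generate_reference_waveforms()] result or a list with
#'   the same structure.
#' @param sqi_window_s SQI window length in seconds.
#' @return Data frame with `time`, `ref_hr`, `ref_hr_valid`, `ref_rr`,
#'   `ref_rr_valid`.
#' @export
reference_vitals <- function(waveforms, sqi_window_s = 10) {
  num <- waveforms$numerics
  n <- nrow(num)
  win_sqi <- function(wave) {
    vapply(num$time, function(s) {
      i1 <- min(length(wave$x), round(s * wave$fs))
      i0 <- max(1L, i1 - round(sqi_window_s * wave$fs) + 1L)
      if (i1 - i0 < 2 * wave$fs) return(0)
      if (identical(wave$fs, waveforms$ecg$fs)) ecg_sqi(wave$x[i0:i1], wave$fs)
      else ppg_sqi(wave$x[i0:i1], wave$fs)
    }, 0)
  }
  sqi_e <- win_sqi(waveforms$ecg)
  sqi_p <- win_sqi(waveforms$ppg)
  rhr <- reference_hr(num$hr_ecg, num$hr_ppg, sqi_e, sqi_p)
  sur <- derive_resp_surrogates(waveforms$ecg)
  rrr <- reference_rr(sur, waveforms$ip)
  rr_val <- rep(NA_real_, n)
  rr_ok <- rep(FALSE, n)
  m <- match(num$time, rrr$time)
  has <- !is.na(m)
  rr_val[has] <- rrr$value[m[has]]
  rr_ok[has] <- rrr$valid[m[has]]
  data.frame(time = num$time, ref_hr = rhr$value, ref_hr_valid = rhr$valid,
             ref_rr = rr_val, ref_rr_valid = rr_ok)
}
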