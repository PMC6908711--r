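# Twelve-channel respiratory signal extraction, breath detection,
# per-window quality and multi-channel Kalman fusion.

RESP_CHANNELS <- c("ppgi_red", "ppgi_green", "ppgi_blue",
                   "skin_area", "skin_perimeter",
                   "skin_centroid_x", "skin_centroid_y",
                   "ellipse_major", "ellipse_minor", "ellipse_orientation",
                   "ellipse_eccentricity", "ellipse_area")

#' Fit an ellipse to a binary mask by second central moments
#'
#' Matches the second central moments of the largest set of `TRUE` pixels to
#' an ellipse: axis lengths are `4 * sqrt(eigenvalue)` of the 2x2 central
#' covariance of pixel coordinates (with the 1/12 pixel-spread correction),
#' the orientation is the principal-axis angle wrapped to `(-pi/2, pi/2]`,
#' eccentricity is `sqrt(1 - (minor/major)^2)` and the area is
#' `pi * major * minor / 4`.
#'
#' @param mask Logical (or 0/1) matrix. The caller is responsible for
#'   passing a single connected region if that is intended.
#' @return List with `centre` (x = column, y = row), `major`, `minor`
#'   (full axis lengths, px), `orientation` (radians), `eccentricity`,
#'   `area` and `valid`. Fewer than 5 pixels gives `valid = FALSE`.
#' @export
fit_ellipse <- function(mask) {
  idx <- which(mask != 0, arr.ind = TRUE)
  n <- nrow(idx)
  invalid <- list(centre = c(x = NA_real_, y = NA_real_), major = NA_real_,
                  minor = NA_real_, orientation = NA_real_,
                  eccentricity = NA_real_, area = NA_real_, valid = FALSE)
  if (n < 5) return(invalid)
  y <- idx[, 1]
  x <- idx[, 2]
  mx <- mean(x); my <- mean(y)
  # central second moments with the unit-pixel spread correction
  cxx <- mean((x - mx)^2) + 1 / 12
  cyy <- mean((y - my)^2) + 1 / 12
  cxy <- mean((x - mx) * (y - my))
  C <- matrix(c(cxx, cxy, cxy, cyy), 2, 2)
  e <- eigen(C, symmetric = TRUE)
  major <- 4 * sqrt(e$values[1])
  minor <- 4 * sqrt(max(e$values[2], 0))
  v <- e$vectors[, 1]
  theta <- atan2(v[2], v[1])
  if (theta <= -pi / 2) theta <- theta + pi
  if (theta > pi / 2) theta <- theta - pi
  list(centre = c(x = mx, y = my), major = major, minor = minor,
       orientation = theta,
       eccentricity = sqrt(max(0, 1 - (minor / major)^2)),
       area = pi * major * minor / 4, valid = TRUE)
}

# City-block perimeter: number of 4-adjacency skin/non-skin transitions,
# including the image border.
mask_perimeter <- function(m) {
  m <- m != 0
  nr <- nrow(m); nc <- ncol(m)
  p <- sum(m[-1, ] != m[-nr, ]) + sum(m[, -1] != m[, -nc])
  p + sum(m[1, ]) + sum(m[nr, ]) + sum(m[, 1]) + sum(m[, nc])
}

largest_component <- function(m) {
  lab <- EBImage::bwlabel(EBImage::Image(m * 1))
  lab <- EBImage::imageData(lab)
  if (max(lab) <= 1) return(m != 0)
  counts <- tabulate(lab[lab > 0])
  lab == which.max(counts)
}

#' Extract the twelve respiratory channel signals
#'
#' Group 1: the raw PPGi signals of the three colour channels. Group 2:
#' area, city-block perimeter and centroid x/y of the entire skin label.
#' Group 3: major/minor axis, orientation, eccentricity and area of the
#' ellipse moment-matched to the largest connected skin region. Frames with
#' an empty mask yield an invalid sample in all twelve channels.
#'
#' @param frames A `frame_stream` or list of frame arrays.
#' @param masks `function(i)` or list of per-frame binary masks.
#' @return Named list of twelve [ppgi_signal()] objects (see
#'   `neovitals:::RESP_CHANNELS` for the names), all sampled at the frame
#'   rate with a shared validity pattern.
#' @export
extract_resp_signals <- function(frames, masks) {
  if (inherits(frames, "frame_stream")) {
    n <- frames$n
    get_frame <- frames$get_frame
    fs <- frames$frame_rate
  } else {
    n <- length(frames)
    get_frame <- function(i) frames[[i]]
    fs <- attr(frames, "frame_rate") %||% 20
  }
  mask_fun <- resolve_masks(masks, n)
  vals <- matrix(NA_real_, n, length(RESP_CHANNELS),
                 dimnames = list(NULL, RESP_CHANNELS))
  for (i in seq_len(n)) {
    m <- mask_fun(i)
    ns <- sum(m)
    if (ns == 0) next
    fr <- get_frame(i)
    vals[i, "ppgi_red"] <- sum(fr[, , 1][m]) / ns
    vals[i, "ppgi_green"] <- sum(fr[, , 2][m]) / ns
    vals[i, "ppgi_blue"] <- sum(fr[, , 3][m]) / ns
    vals[i, "skin_area"] <- ns
    vals[i, "skin_perimeter"] <- mask_perimeter(m)
    idx <- which(m != 0, arr.ind = TRUE)
    vals[i, "skin_centroid_x"] <- mean(idx[, 2])
    vals[i, "skin_centroid_y"] <- mean(idx[, 1])
    ef <- fit_ellipse(largest_component(m))
    if (ef$valid) {
      vals[i, "ellipse_major"] <- ef$major
      vals[i, "ellipse_minor"] <- ef$minor
      vals[i, "ellipse_orientation"] <- ef$orientation
      vals[i, "ellipse_eccentricity"] <- ef$eccentricity
      vals[i, "ellipse_area"] <- ef$area
    }
  }
  # a frame that is invalid in any channel is invalid in all twelve
  valid <- stats::complete.cases(vals)
  out <- lapply(RESP_CHANNELS, function(ch) {
    x <- vals[, ch]
    x[!valid] <- NA
    ppgi_signal(x, fs, valid = valid, channel = ch)
  })
  names(out) <- RESP_CHANNELS
  out
}

#' Detect breaths by mean-average-curve crossings
#'
#' The mean average curve (MAC) is a centred moving average of the filtered
#' respiratory signal (window `mac_window_s`). A breath onset is an upward
#' crossing of the signal through the MAC, subject to a 500 ms refractory
#' period; the breath peak is the signal maximum before the next downward
#' crossing.
#'
#' @param sig Respiratory-filtered [ppgi_signal()].
#' @param mac_window_s MAC window length in seconds.
#' @param refractory_s Minimum onset-to-onset separation in seconds.
#' @return Data frame with `onset`, `peak`, `onset_idx`, `peak_idx`,
#'   `amplitude`.
#' @export
detect_breaths_mac <- function(sig, mac_window_s = 2, refractory_s = 0.5) {
  x <- sig$x
  x[!sig$valid | !is.finite(x)] <- 0
  fs <- sig$fs
  n <- length(x)
  empty <- data.frame(onset = numeric(0), peak = numeric(0),
                      onset_idx = integer(0), peak_idx = integer(0),
                      amplitude = numeric(0))
  w <- max(3L, round(mac_window_s * fs))
  if (n < w + 2) return(empty)
  mac <- as.numeric(stats::filter(x, rep(1 / w, w), sides = 2))
  mac <- zoo::na.locf(zoo::na.locf(mac, na.rm = FALSE), fromLast = TRUE)
  d <- x - mac
  if (all(d == 0)) return(empty)
  up <- which(d[-1] > 0 & d[-n] <= 0) + 1L
  down <- which(d[-1] <= 0 & d[-n] > 0) + 1L
  refr <- max(1L, floor(refractory_s * fs))
  onsets <- integer(0); peaks <- integer(0)
  last <- -Inf
  for (o in up) {
    if (o - last <= refr) next
    nd <- down[down > o]
    e <- if (length(nd)) nd[1] else n
    pk <- o + which.max(x[o:e]) - 1L
    if (pk > o || x[pk] > x[max(1, o - 1)]) {
      onsets <- c(onsets, o)
      peaks <- c(peaks, pk)
      last <- o
    }
  }
  keep <- !duplicated(peaks)
  onsets <- onsets[keep]; peaks <- peaks[keep]
  data.frame(onset = sig$t0 + (onsets - 1) / fs,
             peak = sig$t0 + (peaks - 1) / fs,
             onset_idx = onsets, peak_idx = peaks,
             amplitude = x[peaks] - x[onsets])
}

#' Detect breaths by the boxed slope-sum function
#'
#' The cardiac slope-sum detector with the upslope window widened to 300 ms
#' (six samples at 20 Hz) and a 500 ms refractory period.
#'
#' @param sig Respiratory-filtered [ppgi_signal()].
#' @param upslope_s Upslope window in seconds.
#' @param refractory_s Refractory period in seconds.
#' @return Data frame as in [detect_breaths_mac()].
#' @export
detect_breaths_bssf <- function(sig, upslope_s = 0.300, refractory_s = 0.5) {
  x <- sig$x
  x[!sig$valid | !is.finite(x)] <- 0
  ev <- slope_sum_detect(x, sig$fs, upslope_s = upslope_s,
                         refractory_s = refractory_s)
  ev$onset <- ev$onset + sig$t0
  ev$peak <- ev$peak + sig$t0
  ev
}

# Per-breath gates and DTW scores for one channel (BSSF events drive the
# scoring; MAC provides the count cross-check at window level).
score_breaths <- function(breaths, sig, activity = NULL,
                          rate_range = c(18, 120), tau = 0.5,
                          template_alpha = 0.1, template_reset_s = 30) {
  nb <- nrow(breaths)
  if (nb == 0) {
    breaths$gate_activity <- logical(0)
    breaths$gate_rate <- logical(0)
    breaths$dtw_score <- numeric(0)
    breaths$sqi <- numeric(0)
    return(breaths)
  }
  x <- sig$x
  x[!sig$valid | !is.finite(x)] <- 0
  fs <- sig$fs
  active_secs <- if (is.null(activity)) integer(0) else
    activity$second[activity$active]
  g_act <- g_rate <- rep(TRUE, nb)
  dtw_score <- rep(NA_real_, nb)
  template <- NULL
  last_accept_t <- -Inf
  for (b in seq_len(nb)) {
    secs <- floor(breaths$onset[b]):floor(breaths$peak[b])
    g_act[b] <- !any(secs %in% active_secs)
    if (b > 1) {
      rate <- 60 / (breaths$peak[b] - breaths$peak[b - 1])
      g_rate[b] <- rate >= rate_range[1] && rate <= rate_range[2]
    }
    gates_ok <- g_act[b] && g_rate[b]
    end_idx <- if (b < nb) breaths$onset_idx[b + 1] else
      min(breaths$onset_idx[b] + ceiling(3 * fs), length(x))
    shape <- normalise_shape(x[breaths$onset_idx[b]:end_idx])
    if (!is.null(shape)) {
      if (!is.null(template) &&
          breaths$peak[b] - last_accept_t > template_reset_s)
        template <- NULL
      if (is.null(template)) {
        dtw_score[b] <- 1
        if (gates_ok) template <- shape
      } else {
        dtw_score[b] <- dtw_similarity(shape, template, tau)
        if (gates_ok)
          template <- (1 - template_alpha) * template + template_alpha * shape
      }
      if (gates_ok) last_accept_t <- breaths$peak[b]
    } else dtw_score[b] <- 0
  }
  breaths$gate_activity <- g_act
  breaths$gate_rate <- g_rate
  breaths$dtw_score <- dtw_score
  breaths$sqi <- ifelse(g_act & g_rate, dtw_score, 0)
  breaths
}

#' Respiratory window signal quality
#'
#' The two breath detectors must agree: when the MAC and BSSF breath counts
#' in the window differ the SQI is 0. Otherwise the SQI is the mean over the
#' window's scored breaths of the per-breath combined score (activity gate
#' times physiological-range gate times DTW similarity).
#'
#' @param window `c(start, end)` seconds.
#' @param mac_events Data frame from [detect_breaths_mac()].
#' @param bssf_scored Scored BSSF breaths from the internal breath scorer.
#' @param activity Optional [activity_index()] result (re-checked at window
#'   level so a fully active window scores 0 even without detected breaths).
#' @return SQI in `[0, 1]`.
#' @export
resp_window_sqi <- function(window, mac_events, bssf_scored,
                            activity = NULL) {
  n_mac <- sum(mac_events$peak >= window[1] & mac_events$peak <= window[2])
  in_w <- bssf_scored$peak >= window[1] & bssf_scored$peak <= window[2]
  n_bssf <- sum(in_w)
  if (n_mac != n_bssf) return(0)
  if (!is.null(activity)) {
    secs <- floor(window[1]):ceiling(window[2] - 1)
    if (any(secs %in% activity$second[activity$active])) return(0)
  }
  if (n_bssf == 0) return(0)
  mean(bssf_scored$sqi[in_w])
}

#' Respiratory rate by breath counting
#'
#' Expands the window to the span of complete breaths and counts intervals:
#' `RR = (n_peaks - 1) * 60 / span`, invalid outside `rate_range` or with
#' fewer than two breaths.
#'
#' @param peak_times Breath peak times in seconds.
#' @param window `c(start, end)` seconds.
#' @param rate_range Valid range in breaths/min.
#' @return List with `value`, `valid`, `method`, `fallback`.
#' @export
rr_estimate <- function(peak_times, window, rate_range = c(18, 120)) {
  out <- hr_beat_counting(peak_times, window, rate_range = rate_range,
                          max_gap = 60 / rate_range[1])
  out$method <- "resp_count"
  out
}

#' Estimate respiratory rate for every channel
#'
#' Filters each of the twelve respiratory channels to the breathing band,
#' runs both breath detectors, scores breaths, and produces a 1 Hz estimate
#' series per channel using a 10 s sliding window (first estimate at 10 s,
#' stamped at the window end).
#'
#' @param resp_signals Named list from [extract_resp_signals()].
#' @param activity Optional [activity_index()] result.
#' @param window_s Window length in seconds.
#' @param rate_range Valid range in breaths/min.
#' @return Named list of per-channel data frames (`time`, `value`, `sqi`,
#'   `valid`).
#' @export
estimate_rr_channels <- function(resp_signals, activity = NULL,
                                 window_s = 10, rate_range = c(18, 120)) {
  lapply(resp_signals, function(sig) {
    duration <- length(sig$x) / sig$fs
    ends <- seq(window_s, floor(duration), by = 1)
    res <- data.frame(time = ends, value = NA_real_, sqi = 0, valid = FALSE)
    filt <- tryCatch(filter_respiratory(sig), error = function(e) NULL)
    if (is.null(filt) || !any(filt$valid)) return(res)
    mac <- detect_breaths_mac(filt)
    bssf <- detect_breaths_bssf(filt)
    bssf <- score_breaths(bssf, filt, activity, rate_range = rate_range)
    good_peaks <- bssf$peak[bssf$sqi > 0]
    for (k in seq_along(ends)) {
      win <- c(ends[k] - window_s, ends[k])
      est <- rr_estimate(good_peaks, win, rate_range)
      sqi <- resp_window_sqi(win, mac, bssf, activity)
      res$value[k] <- est$value
      res$sqi[k] <- sqi
      res$valid[k] <- est$valid && sqi > 0
    }
    res
  })
}

#' Fuse per-channel respiratory estimates
#'
#' Runs one SQI-weighted random-walk Kalman filter per channel (as for
#' heart rate, with the respiratory range) and combines the channel
#' posteriors with weights `w_i = sqi_i / posterior_variance_i` over
#' channels with positive SQI. The fused value is the weighted median of
#' the channel posteriors: a minority of channels can lock onto a harmonic
#' or sub-harmonic of the breathing rate with internally consistent, high
#' quality, and a weighted mean would be pulled toward them, while the
#' weighted median follows the channel consensus. The fused SQI is the
#' weighted mean of the channel SQIs; a second with no positive-SQI channel
#' is invalid.
#'
#' @param channel_estimates Named list of per-channel estimate data frames
#'   (from [estimate_rr_channels()]).
#' @param range Valid output range in breaths/min.
#' @param q,r Kalman process/measurement variance parameters.
#' @return Data frame with `time`, `value`, `sqi`, `valid`.
#' @export
fuse_rr <- function(channel_estimates, range = c(18, 120), q = 4, r = 4) {
  stopifnot(length(channel_estimates) >= 1)
  times <- channel_estimates[[1]]$time
  ks <- lapply(channel_estimates, function(ce) {
    stopifnot(identical(ce$time, times))
    kalman_smooth(ce$value, ce$sqi, ce$valid, q = q, r = r, range = range)
  })
  nt <- length(times)
  value <- rep(NA_real_, nt)
  sqi <- rep(0, nt)
  for (t in seq_len(nt)) {
    v <- vapply(ks, function(k) k$value[t], 0)
    p <- vapply(ks, function(k) k$variance[t], 0)
    s <- vapply(channel_estimates, function(ce) ce$sqi[t], 0)
    use <- s > 0 & is.finite(v) & is.finite(p) & p > 0
    if (!any(use)) next
    w <- s[use] / p[use]
    value[t] <- weighted_median(v[use], w)
    sqi[t] <- sum(w * s[use]) / sum(w)
  }
  data.frame(time = times, value = value, sqi = sqi,
             valid = is.finite(value) & sqi > 0)
}
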