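#' Scene configuration for the synthetic video generator
#'
#' Describes a synthetic recording of a skin-coloured elliptical subject on a
#' darker background. The green channel over the ellipse carries a cardiac
#' pulse waveform (fundamental plus one harmonic), the ellipse minor axis and
#' vertical centroid are modulated at the respiratory rate, and optional
#' motion bursts, lighting steps and absence intervals emulate the main
#' disturbances seen in incubator video.
#'
#' @param duration Scene length in seconds.
#' @param frame_rate Frames per second (nominally 20).
#' @param frame_size Integer vector `c(rows, cols)` of the pixel grid.
#' @param hr_schedule Heart rate in beats/min: a scalar, a `function(t)`, or a
#'   `data.frame(time, value)` step schedule. Values must lie in [90, 270].
#' @param rr_schedule Respiratory rate in breaths/min (scalar, function or
#'   step data frame); values must lie in [18, 120].
#' @param ppgi_amplitude Fractional modulation depth of the green channel at
#'   the cardiac frequency.
#' @param shape_amplitude Fractional modulation depth of the ellipse minor
#'   axis at the respiratory frequency.
#' @param motion_bursts List of `c(start, end, amplitude_px)` translation
#'   bursts.
#' @param lighting_steps List of `c(time, factor)` multiplicative brightness
#'   steps applied from `time` onwards.
#' @param absence_intervals List of `c(start, end)` intervals during which the
#'   subject is absent (background only, empty skin mask).
#' @param noise_sd Standard deviation of additive per-pixel Gaussian noise
#'   (intensity units). Independent across pixels, so it largely averages
#'   out of region-mean signals.
#' @param flicker_sd Fractional standard deviation of the shared per-frame
#'   illumination fluctuation (ambient-light and camera-gain flicker).
#'   Common to all pixels of a frame, it sets the noise floor of the
#'   region-averaged PPGi signals; 0 disables it.
#' @param skin_rgb Mean skin colour (RGB, 0-255).
#' @param bg_rgb Mean background colour (RGB, 0-255).
#' @param texture_sd Standard deviation of the static per-pixel colour
#'   texture.
#' @param timestamp_jitter_sd Standard deviation (seconds) of optional frame
#'   timestamp jitter; 0 gives exactly uniform sampling.
#' @param seed Integer RNG seed; identical configurations produce
#'   bit-identical scenes.
#'
#' @return An object of class `scene_config`.
#' @export
scene_config <- function(duration,
                         frame_rate = 20,
                         frame_size = c(120, 160),
                         hr_schedule = 140,
                         rr_schedule = 50,
                         ppgi_amplitude = 0.03,
                         shape_amplitude = 0.03,
                         motion_bursts = list(),
                         lighting_steps = list(),
                         absence_intervals = list(),
                         noise_sd = 1,
                         flicker_sd = 0.003,
                         skin_rgb = c(224, 172, 150),
                         bg_rgb = c(56, 64, 76),
                         texture_sd = 6,
                         timestamp_jitter_sd = 0,
                         seed = 1L) {
  stopifnot(duration > 0, frame_rate > 0, length(frame_size) == 2)
  hr_fun <- as_schedule(hr_schedule)
  rr_fun <- as_schedule(rr_schedule)
  tt <- seq(0, duration, by = 1)
  hr <- hr_fun(tt)
  rr <- rr_fun(tt)
  if (any(hr < 90 | hr > 270))
    stop("hr_schedule values must lie in [90, 270] beats/min")
  if (any(rr < 18 | rr > 120))
    stop("rr_schedule values must lie in [18, 120] breaths/min")
  chk_iv <- function(iv, what, len) {
    for (v in iv) {
      if (length(v) != len || v[1] < 0 || v[2] > duration ||
          (len >= 2 && v[2] <= v[1] && what != "lighting"))
        stop(sprintf("invalid %s interval", what))
    }
  }
  chk_iv(motion_bursts, "motion", 3)
  chk_iv(absence_intervals, "absence", 2)
  for (v in lighting_steps)
    if (length(v) != 2 || v[1] < 0 || v[1] > duration || v[2] <= 0)
      stop("invalid lighting step")
  for (a in absence_intervals)
    for (m in motion_bursts)
      if (a[1] < m[2] && m[1] < a[2])
        stop("absence intervals must not overlap motion bursts: ",
             "the subject cannot move while absent")
  structure(list(
    duration = duration, frame_rate = frame_rate,
    frame_size = as.integer(frame_size),
    hr_fun = hr_fun, rr_fun = rr_fun,
    ppgi_amplitude = ppgi_amplitude, shape_amplitude = shape_amplitude,
    motion_bursts = motion_bursts, lighting_steps = lighting_steps,
    absence_intervals = absence_intervals,
    noise_sd = noise_sd, flicker_sd = flicker_sd,
    skin_rgb = skin_rgb, bg_rgb = bg_rgb,
    texture_sd = texture_sd, timestamp_jitter_sd = timestamp_jitter_sd,
    seed = as.integer(seed)
  ), class = "scene_config")
}

in_any_interval <- function(t, intervals) {
  if (length(intervals) == 0) return(rep(FALSE, length(t)))
  out <- rep(FALSE, length(t))
  for (v in intervals) out <- out | (t >= v[1] & t < v[2])
  out
}

#' Generate a synthetic scene with known ground truth
#'
#' Renders the scene described by a [scene_config()] as a lazily-evaluated
#' frame stream (frames are computed on demand so long scenes do not need to
#' be held in memory) together with its ground truth: 1 Hz heart-rate and
#' respiratory-rate series, per-second presence, true beat and breath times,
#' and per-frame skin masks.
#'
#' @param config A [scene_config()].
#' @return A list of class `scene` with elements `frames` (a `frame_stream`
#'   with `n`, `frame_rate`, `timestamps`, `get_frame(i)` returning a
#'   rows x cols x 3 intensity array in [0, 255]) and `truth` (heart/resp
#'   series, `presence`, `beat_times`, `breath_times`, `get_mask(i)`).
#' @export
generate_scene <- function(config) {
  stopifnot(inherits(config, "scene_config"))
  fs <- config$frame_rate
  n <- as.integer(round(config$duration * fs))
  nr <- config$frame_size[1]
  nc <- config$frame_size[2]
  t_frames <- (seq_len(n) - 1) / fs
  if (config$timestamp_jitter_sd > 0) {
    jit <- with_local_seed(sub_seed(config$seed, 999983L),
                           stats::rnorm(n, 0, config$timestamp_jitter_sd))
    t_frames <- pmax(0, t_frames + jit)
  }

  # phase on a fine grid so beat/breath event times are accurate to 2 ms
  dt_fine <- 0.002
  t_fine <- seq(0, config$duration, by = dt_fine)
  phi_c <- phase_integral(config$hr_fun, config$duration, dt_fine)
  phi_r <- phase_integral(config$rr_fun, config$duration, dt_fine)
  beat_times <- phase_event_times(t_fine, phi_c)
  breath_times <- phase_event_times(t_fine, phi_r)
  phi_c_f <- stats::approx(t_fine, phi_c, xout = t_frames, rule = 2)$y
  phi_r_f <- stats::approx(t_fine, phi_r, xout = t_frames, rule = 2)$y

  light <- rep(1, n)
  for (v in config$lighting_steps) light[t_frames >= v[1]] <- light[t_frames >= v[1]] * v[2]
  if (config$flicker_sd > 0) {
    light <- light * (1 + with_local_seed(sub_seed(config$seed, 999979L),
                                          stats::rnorm(n, 0, config$flicker_sd)))
  }
  absent <- in_any_interval(t_frames, config$absence_intervals)
  dx <- numeric(n); dy <- numeric(n)
  for (v in config$motion_bursts) {
    sel <- t_frames >= v[1] & t_frames < v[2]
    tr <- t_frames[sel] - v[1]
    dx[sel] <- v[3] * sin(2 * pi * 1.3 * tr)
    dy[sel] <- 0.6 * v[3] * sin(2 * pi * 0.9 * tr)
  }

  # static colour texture fields (per channel), fixed for the whole scene
  tex <- lapply(1:3, function(k)
    with_local_seed(sub_seed(config$seed, k),
                    matrix(stats::rnorm(nr * nc, 0, config$texture_sd), nr, nc)))
  X <- matrix(rep(seq_len(nc), each = nr), nr, nc)
  Y <- matrix(rep(seq_len(nr), nc), nr, nc)
  cx0 <- (nc + 1) / 2
  cy0 <- (nr + 1) / 2
  a0 <- 0.30 * nc
  b0 <- 0.27 * nr

  geometry <- function(i) {
    if (absent[i]) return(NULL)
    b_t <- b0 * (1 + config$shape_amplitude * sin(2 * pi * phi_r_f[i]))
    cy_t <- cy0 + 0.5 * b0 * config$shape_amplitude * sin(2 * pi * phi_r_f[i]) + dy[i]
    cx_t <- cx0 + dx[i]
    list(cx = cx_t, cy = cy_t, a = a0, b = b_t)
  }
  make_mask <- function(i) {
    g <- geometry(i)
    if (is.null(g)) return(matrix(FALSE, nr, nc))
    ((X - g$cx) / g$a)^2 + ((Y - g$cy) / g$b)^2 <= 1
  }
  pulse <- function(phi) sin(2 * pi * phi) + 0.3 * sin(4 * pi * phi)

  get_frame <- function(i) {
    stopifnot(i >= 1, i <= n)
    m <- make_mask(i)
    ch <- vector("list", 3)
    for (k in 1:3) {
      plane <- config$bg_rgb[k] + tex[[k]]
      if (any(m)) {
        val <- config$skin_rgb[k]
        if (k == 2L)
          val <- val * (1 + config$ppgi_amplitude * pulse(phi_c_f[i]))
        plane[m] <- val + tex[[k]][m]
      }
      ch[[k]] <- plane * light[i]
    }
    fr <- array(0, dim = c(nr, nc, 3))
    fr[, , 1] <- ch[[1]]; fr[, , 2] <- ch[[2]]; fr[, , 3] <- ch[[3]]
    if (config$noise_sd > 0) {
      fr <- fr + with_local_seed(sub_seed(config$seed, 1000L + i),
                                 array(stats::rnorm(nr * nc * 3, 0, config$noise_sd),
                                       dim = c(nr, nc, 3)))
    }
    fr[fr < 0] <- 0
    fr[fr > 255] <- 255
    fr
  }

  sec <- 0:(ceiling(config$duration) - 1)
  truth <- list(
    hr_series = data.frame(time = sec, hr = config$hr_fun(sec + 0.5)),
    rr_series = data.frame(time = sec, rr = config$rr_fun(sec + 0.5)),
    presence = !in_any_interval(sec + 0.5, config$absence_intervals),
    beat_times = beat_times,
    breath_times = breath_times,
    motion_bursts = config$motion_bursts,
    absence_intervals = config$absence_intervals,
    get_mask = make_mask
  )
  frames <- structure(list(
    n = n, frame_rate = fs, timestamps = t_frames,
    frame_size = config$frame_size, get_frame = get_frame
  ), class = "frame_stream")
  structure(list(frames = frames, truth = truth, config = config),
            class = "scene")
}

#' @export
print.scene <- function(x, ...) {
  cat(sprintf("<scene> %.0f s @ %g fps, %d x %d px, %d frames\n",
              x$config$duration, x$config$frame_rate,
              x$config$frame_size[1], x$config$frame_size[2], x$frames$n))
  invisible(x)
}

#' Generate matched reference monitor waveforms
#'
#' Simulates the monitor waveforms recorded alongside the video: a 500 Hz
#' single-lead ECG built from a QRS template train whose R-peak amplitude and
#' baseline are modulated at the respiratory rate (so ECG-derived respiration
#' surrogates are recoverable), a 125 Hz PPG pulse train with a systolic peak
#' and dicrotic notch, a 64 Hz near-sinusoidal impedance pneumography trace,
#' and 1 Hz monitor numerics computed from the event times.
#'
#' @param hr_schedule,rr_schedule As in [scene_config()].
#' @param duration Length in seconds.
#' @param seed Integer RNG seed.
#' @param noise_sd Additive waveform noise (fraction of unit amplitude).
#' @return A list of class `reference_waveforms` with elements `ecg`, `ppg`,
#'   `ip` (each `list(t, x, fs)`), `numerics` (1 Hz data frame with columns
#'   `time`, `hr_ecg`, `hr_ppg`, `rr_ip`, `spo2`), `beat_times` and
#'   `breath_times`.
#' @export
generate_reference_waveforms <- function(hr_schedule, rr_schedule, duration,
                                         seed = 1L, noise_sd = 0.02) {
  hr_fun <- as_schedule(hr_schedule)
  rr_fun <- as_schedule(rr_schedule)
  tt <- seq(0, duration, by = 1)
  if (any(hr_fun(tt) < 90 | hr_fun(tt) > 270))
    stop("hr_schedule values must lie in [90, 270] beats/min")
  if (any(rr_fun(tt) < 18 | rr_fun(tt) > 120))
    stop("rr_schedule values must lie in [18, 120] breaths/min")

  dt_fine <- 0.002
  t_fine <- seq(0, duration, by = dt_fine)
  phi_c <- phase_integral(hr_fun, duration, dt_fine)
  phi_r <- phase_integral(rr_fun, duration, dt_fine)
  beat_times <- phase_event_times(t_fine, phi_c)
  breath_times <- phase_event_times(t_fine, phi_r)
  resp_phase <- function(t) stats::approx(t_fine, phi_r, xout = t, rule = 2)$y

  add_template <- function(x, t, centre, amp, sd) {
    i0 <- max(1L, ceiling((centre - 4 * sd - t[1]) / (t[2] - t[1])) + 1L)
    i1 <- min(length(t), floor((centre + 4 * sd - t[1]) / (t[2] - t[1])) + 1L)
    if (i1 < i0) return(x)
    idx <- i0:i1
    x[idx] <- x[idx] + amp * exp(-0.5 * ((t[idx] - centre) / sd)^2)
    x
  }

  # ECG: Q/R/S Gaussian bumps per beat; R amplitude and baseline modulated
  # at the respiratory phase
  fs_ecg <- 500
  t_ecg <- seq(0, duration - 1 / fs_ecg, by = 1 / fs_ecg)
  ecg <- 0.05 * sin(2 * pi * resp_phase(t_ecg))
  for (tb in beat_times) {
    r_amp <- 1 + 0.3 * sin(2 * pi * resp_phase(tb))
    ecg <- add_template(ecg, t_ecg, tb, r_amp, 0.008)
    ecg <- add_template(ecg, t_ecg, tb - 0.028, -0.12 * r_amp, 0.008)
    ecg <- add_template(ecg, t_ecg, tb + 0.028, -0.20 * r_amp, 0.008)
  }

  # PPG: systolic peak plus dicrotic notch placed at fractions of each
  # inter-beat interval
  fs_ppg <- 125
  t_ppg <- seq(0, duration - 1 / fs_ppg, by = 1 / fs_ppg)
  ppg <- numeric(length(t_ppg))
  if (length(beat_times) >= 2) {
    ibis <- diff(beat_times)
    ibis <- c(ibis, ibis[length(ibis)])
    for (k in seq_along(beat_times)) {
      tb <- beat_times[k]; ibi <- ibis[k]
      ppg <- add_template(ppg, t_ppg, tb + 0.25 * ibi, 1, 0.12 * ibi)
      ppg <- add_template(ppg, t_ppg, tb + 0.58 * ibi, 0.35, 0.08 * ibi)
    }
  }

  fs_ip <- 64
  t_ip <- seq(0, duration - 1 / fs_ip, by = 1 / fs_ip)
  ip <- sin(2 * pi * resp_phase(t_ip))

  if (noise_sd > 0) {
    ecg <- ecg + with_local_seed(sub_seed(seed, 11L),
                                 stats::rnorm(length(ecg), 0, noise_sd))
    ppg <- ppg + with_local_seed(sub_seed(seed, 12L),
                                 stats::rnorm(length(ppg), 0, noise_sd))
    ip <- ip + with_local_seed(sub_seed(seed, 13L),
                               stats::rnorm(length(ip), 0, noise_sd))
  }

  # 1 Hz numerics derived from event times (interval convention over a
  # trailing window)
  rate_from_events <- function(ev, t_end, win) {
    sel <- ev > t_end - win & ev <= t_end
    if (sum(sel) < 2) return(NA_real_)
    e <- ev[sel]
    (length(e) - 1) * 60 / (e[length(e)] - e[1])
  }
  sec <- seq_len(floor(duration))
  hr_ecg_num <- vapply(sec, function(s) rate_from_events(beat_times, s, 8), 0)
  jitter <- with_local_seed(sub_seed(seed, 14L),
                            stats::rnorm(length(sec), 0, 0.3))
  hr_ppg_num <- hr_ecg_num + jitter
  rr_ip_num <- vapply(sec, function(s) rate_from_events(breath_times, s, 20), 0)
  numerics <- data.frame(time = sec, hr_ecg = hr_ecg_num, hr_ppg = hr_ppg_num,
                         rr_ip = rr_ip_num, spo2 = 97)

  structure(list(
    ecg = list(t = t_ecg, x = ecg, fs = fs_ecg),
    ppg = list(t = t_ppg, x = ppg, fs = fs_ppg),
    ip = list(t = t_ip, x = ip, fs = fs_ip),
    numerics = numerics,
    beat_times = beat_times, breath_times = breath_times
  ), class = "reference_waveforms")
}
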