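# Internal numerical helpers shared across modules.

# Evaluate a function body with a locally-seeded RNG stream, restoring the
# caller's .Random.seed afterwards.  Used for reproducible per-frame noise.
with_local_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = .GlobalEnv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = .GlobalEnv) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = .GlobalEnv)
    else if (exists(".Random.seed", envir = .GlobalEnv, inherits = FALSE))
      rm(".Random.seed", envir = .GlobalEnv)
  })
  set.seed(seed)
  force(expr)
}

# Deterministic sub-seed derived from a master seed and an index, kept in
# 32-bit integer range.
sub_seed <- function(seed, index) {
  as.integer((as.numeric(seed) * 48271 + as.numeric(index) * 16807) %%
               2147483647)
}

# Piecewise-constant schedule: accepts a scalar, a function(t), or a
# data.frame(time, value) giving the value from `time` onwards.
as_schedule <- function(x) {
  if (is.function(x)) return(x)
  if (is.numeric(x) && length(x) == 1L) {
    force(x)
    return(function(t) rep(x, length(t)))
  }
  if (is.data.frame(x) && all(c("time", "value") %in% names(x))) {
    o <- order(x$time)
    times <- x$time[o]
    values <- x$value[o]
    return(function(t) values[pmax(1L, findInterval(t, times))])
  }
  stop("schedule must be a scalar, a function(t), or a data.frame(time, value)")
}

# Cumulative phase (in cycles) of a rate schedule given in events/min,
# evaluated on a uniform grid of step dt starting at 0.
phase_integral <- function(schedule_fun, duration, dt) {
  t <- seq(0, duration, by = dt)
  f <- schedule_fun(t) / 60
  c(0, cumsum((f[-1] + f[-length(f)]) / 2 * dt))
}

# Times at which a monotone phase (cycles) crosses successive integers.
phase_event_times <- function(t, phase) {
  n_events <- floor(phase[length(phase)])
  if (n_events < 1) return(numeric(0))
  stats::approx(phase, t, xout = seq_len(n_events), ties = "ordered")$y
}

# Windowed sum of positive first differences (slope-sum transform).
slope_sum <- function(x, w) {
  dx <- pmax(diff(x), 0)
  ssf <- stats::filter(c(numeric(w), dx), rep(1, w), method = "convolution",
                       sides = 1)
  out <- as.numeric(ssf[(w + 1):(w + length(dx))])
  c(0, out)
}

# Linear resampling of a series to n points.
resample_to <- function(x, n) {
  if (length(x) == n) return(x)
  stats::approx(seq_along(x), x, n = n)$y
}

# Length-normalised dynamic time warping distance between two series.
# Cost is |a_i - b_j|; the distance is the optimal path cost divided by the
# path length, so it is comparable across series lengths.
dtw_distance <- function(a, b) {
  n <- length(a)
  m <- length(b)
  if (n == 0L || m == 0L) return(NA_real_)
  big <- .Machine$double.xmax / 4
  D <- matrix(big, n + 1L, m + 1L)
  S <- matrix(0L, n + 1L, m + 1L)   # path length (number of steps)
  D[1L, 1L] <- 0
  for (i in seq_len(n)) {
    cost_i <- abs(a[i] - b)
    for (j in seq_len(m)) {
      prev <- c(D[i, j], D[i, j + 1L], D[i + 1L, j])
      k <- which.min(prev)
      D[i + 1L, j + 1L] <- cost_i[j] + prev[k]
      S[i + 1L, j + 1L] <- 1L + switch(k, S[i, j], S[i, j + 1L], S[i + 1L, j])
    }
  }
  D[n + 1L, m + 1L] / max(S[n + 1L, m + 1L], 1L)
}

# Dominant frequency of a series by zero-padded periodogram within a band.
dominant_frequency <- function(x, fs, fmin = 0, fmax = fs / 2, nfft = 4096) {
  x <- x[is.finite(x)]
  if (length(x) < 4) return(NA_real_)
  x <- x - mean(x)
  nfft <- max(nfft, length(x))
  X <- stats::fft(c(x, numeric(nfft - length(x))))
  f <- (seq_len(nfft) - 1) * fs / nfft
  keep <- f >= fmin & f <= fmax & f <= fs / 2
  if (!any(keep)) return(NA_real_)
  p <- Mod(X[keep])^2
  f[keep][which.max(p)]
}

# Fraction of band power concentrated within +-half_bw of the dominant
# frequency: a cheap spectral-purity quality score in [0, 1].
spectral_purity <- function(x, fs, fmin, fmax, half_bw = 0.15) {
  x <- x[is.finite(x)]
  if (length(x) < 8) return(0)
  x <- x - mean(x)
  nfft <- max(1024, length(x))
  X <- stats::fft(c(x, numeric(nfft - length(x))))
  f <- (seq_len(nfft) - 1) * fs / nfft
  keep <- f >= fmin & f <= fmax & f <= fs / 2
  if (!any(keep)) return(0)
  p <- Mod(X[keep])^2
  fb <- f[keep]
  tot <- sum(p)
  if (tot <= 0) return(0)
  fpk <- fb[which.max(p)]
  sum(p[abs(fb - fpk) <= half_bw]) / tot
}

# Maximal runs of TRUE in a logical vector: data.frame(start, end, length)
# with inclusive indices.
true_runs <- function(flag) {
  r <- rle(flag)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values
  data.frame(start = starts[keep], end = ends[keep], length = r$lengths[keep])
}

# Weighted median: smallest x whose cumulative weight reaches half the
# total (interpolating between the two straddling values at an exact tie).
weighted_median <- function(x, w) {
  o <- order(x)
  x <- x[o]; w <- w[o]
  cw <- cumsum(w) / sum(w)
  k <- which(cw >= 0.5)[1]
  if (k > 1 && abs(cw[k - 1] - 0.5) < 1e-12) (x[k - 1] + x[k]) / 2 else x[k]
}

# Greedy one-to-one matching of two event-time vectors within a tolerance;
# returns the F1 score of the pairing.
match_events_f1 <- function(a, b, tol) {
  if (length(a) == 0L && length(b) == 0L) return(1)
  if (length(a) == 0L || length(b) == 0L) return(0)
  used <- rep(FALSE, length(b))
  tp <- 0L
  for (t in a) {
    d <- abs(b - t)
    d[used] <- Inf
    j <- which.min(d)
    if (d[j] <= tol) {
      tp <- tp + 1L
      used[j] <- TRUE
    }
  }
  prec <- tp / length(a)
  rec <- tp / length(b)
  if (prec + rec == 0) 0 else 2 * prec * rec / (prec + rec)
}
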