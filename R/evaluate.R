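# Validity masking, agreement statistics and gap analysis; plus the
# end-to-end pipeline orchestrator.

#' Combine per-second validity conditions
#'
#' A second of camera data is valid when the patient is present, no
#' clinical intervention is in progress and the reference vitals are
#' mutually consistent. Also summarises the time excluded by each
#' condition.
#'
#' @param presence Logical, patient present.
#' @param no_intervention Logical, no intervention in progress.
#' @param reference_valid Logical, reference values in close agreement.
#' @return List with `valid` (combined AND), and `summary` (seconds total,
#'   per exclusion category, and valid).
#' @export
build_validity_mask <- function(presence, no_intervention, reference_valid) {
  n <- length(presence)
  if (length(no_intervention) != n || length(reference_valid) != n)
    stop("validity inputs have different lengths")
  valid <- presence & no_intervention & reference_valid
  list(valid = valid,
       summary = data.frame(
         total_s = n,
         absent_s = sum(!presence),
         intervention_s = sum(presence & !no_intervention),
         poor_reference_s = sum(presence & no_intervention &
                                  !reference_valid),
         valid_s = sum(valid)))
}

#' Agreement statistics between camera and reference series
#'
#' Computes, over seconds that are valid in the mask and in both series:
#' mean absolute error, bias-removed mean absolute deviation (the mean
#' absolute deviation of the differences about their mean), the median
#' absolute difference, Bland-Altman bias and 95% limits of agreement,
#' pooled Pearson correlation, and the estimated-time percentage (valid
#' camera estimates as a share of valid seconds).
#'
#' @param camera Data frame with `time`, `value`, `valid`.
#' @param reference Data frame with `time`, `value`, `valid`.
#' @param mask Logical per-second validity (aligned to `reference$time`), or
#'   a [build_validity_mask()] result.
#' @return List of class `evaluation_report`.
#' @export
evaluate_vitals <- function(camera, reference, mask = NULL) {
  if (is.list(mask) && !is.null(mask$valid)) mask <- mask$valid
  if (is.null(mask)) mask <- rep(TRUE, nrow(reference))
  if (length(mask) != nrow(reference))
    stop("mask length does not match the reference series")
  ref_ok <- reference$valid & mask
  m <- match(reference$time, camera$time)
  cam_value <- rep(NA_real_, nrow(reference))
  cam_valid <- rep(FALSE, nrow(reference))
  has <- !is.na(m)
  cam_value[has] <- camera$value[m[has]]
  cam_valid[has] <- camera$valid[m[has]] & is.finite(cam_value[has])
  both <- ref_ok & cam_valid
  n_valid <- sum(ref_ok)
  estimated_pct <- if (n_valid == 0) NA_real_ else 100 * sum(both) / n_valid
  if (!any(both)) {
    return(structure(list(empty = TRUE, n = 0, n_valid = n_valid,
                          estimated_pct = estimated_pct,
                          mask = ref_ok, estimated = both),
                     class = "evaluation_report"))
  }
  d <- cam_value[both] - reference$value[both]
  bias <- mean(d)
  sd_d <- stats::sd(d)
  corr <- if (stats::sd(cam_value[both]) == 0 ||
              stats::sd(reference$value[both]) == 0) NA_real_
  else stats::cor(cam_value[both], reference$value[both])
  structure(list(
    empty = FALSE,
    n = sum(both), n_valid = n_valid,
    mae = mean(abs(d)),
    mad = mean(abs(d - bias)),
    median_abs_diff = stats::median(abs(d)),
    bias = bias,
    loa = c(lower = bias - 1.96 * sd_d, upper = bias + 1.96 * sd_d),
    correlation = corr,
    estimated_pct = estimated_pct,
    mask = ref_ok, estimated = both
  ), class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  if (isTRUE(x$empty)) {
    cat("<evaluation_report> empty (no overlapping valid seconds)\n")
    return(invisible(x))
  }
  cat(sprintf(
    "<evaluation_report> n=%d  MAE=%.2f  MAD=%.2f  bias=%.2f  LoA=[%.2f, %.2f]\n  r=%.3f  estimated %.1f%% of %d valid s\n",
    x$n, x$mae, x$mad, x$bias, x$loa[1], x$loa[2],
    x$correlation, x$estimated_pct, x$n_valid))
  invisible(x)
}

#' Gap analysis of estimation coverage
#'
#' Finds maximal runs of valid-but-unestimated seconds, bins their lengths,
#' and reports the estimated-time percentage when gaps up to `allowance_s`
#' are tolerated (treated as estimated).
#'
#' @param estimated Logical per-second: a valid camera estimate exists.
#' @param mask Logical per-second validity.
#' @param allowance_s Gap length (seconds) up to which gaps are bridged.
#' @param breaks Histogram breaks for gap lengths (seconds).
#' @return List with `gaps` (lengths of each gap), `histogram` (table of
#'   binned gap lengths), `raw_pct` and `adjusted_pct`.
#' @export
gap_analysis <- function(estimated, mask, allowance_s = 30,
                         breaks = c(0, 5, 10, 30, 60, 120, Inf)) {
  stopifnot(length(estimated) == length(mask))
  valid_idx <- which(mask)
  if (length(valid_idx) == 0)
    return(list(gaps = integer(0), histogram = table(numeric(0)),
                raw_pct = NA_real_, adjusted_pct = NA_real_))
  # gaps are measured on the valid timeline only
  est_v <- estimated[valid_idx]
  runs <- true_runs(!est_v)
  gaps <- runs$length
  raw_pct <- 100 * mean(est_v)
  bridged <- est_v
  for (r in seq_len(nrow(runs)))
    if (runs$length[r] <= allowance_s)
      bridged[runs$start[r]:runs$end[r]] <- TRUE
  adjusted_pct <- 100 * mean(bridged)
  list(gaps = gaps,
       histogram = table(cut(gaps, breaks = breaks, right = TRUE)),
       raw_pct = raw_pct, adjusted_pct = adjusted_pct)
}

#' Run the full camera vital-sign pipeline on a scene
#'
#' Orchestrates every stage on a synthetic scene: signal extraction from
#' frames and masks, activity index, change-point detection, cardiac
#' filtering, beat detection and scoring, the four heart-rate estimators
#' with Kalman smoothing, the twelve-channel respiratory chain with fusion,
#' and (optionally) reference vitals from matched monitor waveforms.
#'
#' @param scene A [generate_scene()] result.
#' @param masks `"truth"` to use the ground-truth masks, or a `function(i)`
#'   / list of per-frame masks (e.g. from [classify_skin()]).
#' @param reference Optional [generate_reference_waveforms()] result; when
#'   supplied, reference vitals and validity masking are computed.
#' @param hr_methods Heart-rate estimators to run.
#' @return List with `ppgi` (raw and filtered green-channel signals),
#'   `activity`, `changes`, `beats`, `hr` (per-method estimates),
#'   `hr_kalman` (smoothed AR-best series), `resp_channels`, `rr`
#'   (fused respiratory series), and when a reference is supplied
#'   `reference` and `validity`.
#' @export
run_pipeline <- function(scene, masks = "truth", reference = NULL,
                         hr_methods = c("count", "fft", "ar_pole",
                                        "ar_best")) {
  stopifnot(inherits(scene, "scene"))
  mask_fun <- if (identical(masks, "truth")) scene$truth$get_mask
  else resolve_masks(masks, scene$frames$n)

  resp <- extract_resp_signals(scene$frames, mask_fun)
  raw_green <- resp$ppgi_green
  act <- activity_index(mask_fun, n_frames = scene$frames$n,
                        frame_rate = scene$frames$frame_rate)
  changes <- detect_step_changes(raw_green)
  filt <- filter_cardiac(raw_green)
  beats <- score_beats(detect_beats(filt), filt, act, changes)
  hr <- estimate_hr(filt, beats, methods = hr_methods)

  hr_best <- hr[hr$method == "ar_best", ]
  ks <- kalman_smooth(hr_best$value, hr_best$sqi, hr_best$valid)
  hr_kalman <- data.frame(time = hr_best$time, value = ks$value,
                          variance = ks$variance,
                          valid = is.finite(ks$value))

  ce <- estimate_rr_channels(resp, act)
  rr <- fuse_rr(ce)

  out <- list(ppgi = list(raw = raw_green, filtered = filt),
              activity = act, changes = changes, beats = beats,
              hr = hr, hr_kalman = hr_kalman,
              resp_channels = ce, rr = rr)
  if (!is.null(reference)) {
    rv <- reference_vitals(reference)
    sec <- scene$truth$hr_series$time
    pres <- scene$truth$presence
    m <- match(sec, rv$time)
    ref_hr_ok <- rep(FALSE, length(sec))
    ref_hr_ok[!is.na(m)] <- rv$ref_hr_valid[m[!is.na(m)]]
    out$reference <- rv
    out$validity <- build_validity_mask(pres, rep(TRUE, length(sec)),
                                        ref_hr_ok)
  }
  out
}
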