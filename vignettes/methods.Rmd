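---
title: "Camera-based vital-sign estimation: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Camera-based vital-sign estimation: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Preterm infants in intensive care need continuous heart-rate (HR) and
respiratory-rate (RR) monitoring, but adhesive ECG electrodes and pulse
oximeter probes damage fragile skin. A video camera above the incubator can
measure both vital signs without contact: the blood-volume pulse modulates
the intensity of light remitted from the skin (photoplethysmographic
imaging, PPGi), and breathing moves the chest and abdomen, deforming the
visible skin region. `neovitals` implements the full signal chain from
per-frame skin masks to quality-gated, Kalman-fused HR and RR estimates,
together with the construction of a gold-standard reference from monitor
waveforms and the statistics used to evaluate agreement.

## Signal model and processing chain

**PPGi extraction.** With `G_t` the green plane of frame `t` and `S_t` its
binary skin mask with `N_skin` skin pixels, the raw PPGi sample is the
masked spatial mean `sum(G_t * S_t) / N_skin`, sampled at the frame rate
(nominally 20 Hz). Frames with an empty mask produce invalid samples; no
value is interpolated at extraction time. The mean is resolution-free, so
desk-scale frames carry the same signal as full-resolution video.

**Cardiac filtering.** The raw signal is detrended (linear fit removed) and
passed through a cascade of a 40th-order low-pass FIR at 4.5 Hz and a
60th-order high-pass FIR at 1.5 Hz, covering 90–270 beats/min. Taps come
from a Hamming windowed-sinc design (`signal::fir1`); the filter order and
cut-offs are fixed, the design window was the package's choice and the
resulting cascade is verified in the tests to hold gain above −3 dB across
1.8–4.0 Hz and below −20 dB outside 1.0/5.5 Hz at 20 Hz sampling. Each
stage's group delay (`order/2` samples) is compensated so the output stays
time-aligned. Invalid gaps of at most 0.5 s are bridged by linear
interpolation before filtering; longer gaps split the signal into
independently filtered segments so ring-down from one segment cannot leak
across an absence.

**Beat detection.** A slope-sum transform (windowed sum of positive first
differences, window `ceiling(0.150 * fs)` samples — three at 20 Hz —
matching the pulse upslope) is thresholded adaptively: the threshold is
0.6 times a running amplitude estimate, initialised from the first two
seconds, updated as an exponential moving average on each detection, and
decaying with a 5 s half-life while idle so detection recovers after quiet
spells. Detection re-arms only after the transform falls below half the
threshold, which avoids knife-edge misses when the threshold sits exactly
between two quantised levels. A refractory period of 60/270 s (the shortest
physiological beat interval) is enforced between detections, using
`floor(0.222 * fs)` samples so that a rate at the band edge is not rejected
by integer rounding. The onset is placed at the start of the upslope and
the peak at the signal maximum within the supra-threshold run plus one
upslope window.

**Beat quality.** Each beat passes five gates: no overlap with an active
second (subject motion, below), no step change within ±1 s, a preceding
inter-beat interval mapping into 90–270 beats/min, no run of three or more
samples pinned at the beat extremum (clipping), and an amplitude within
0.25–4 times the running median of the last 15 accepted amplitudes. Shape
consistency is scored by dynamic time warping: the beat is resampled to 25
samples, amplitude-normalised, compared against an exponential moving
average template (weight 0.1) at full and half resolution, and the mean
length-normalised distance `d` maps to `exp(-d / 0.5)`. The template resets
after 10 s without an accepted beat. The combined beat SQI is the DTW score
when every gate passes and 0 otherwise; the window SQI is the mean beat SQI
over the estimation window.

**Motion and lighting disturbances.** The activity index is the symmetric
difference of consecutive masks divided by the larger mask area, averaged
per second; a second is active above 0.02 (frames where 2 % of the region
changes). Step changes in the raw PPGi (typically lighting switches) are
found by Bayesian online change-point detection with a constant hazard of
1/300 per sample and a Normal–Gamma observation model on the
robustly-standardised signal; the posterior run-length distribution is
pruned at probability 1e-8, and a collapse of the maximum-a-posteriori run
length marks a change. Samples within ±1 s of a change are excluded.

**Heart-rate estimators.** Estimates are produced for 8 s windows sliding
by 1 s, stamped at the window end (first estimate at 8 s):

* *Beat counting.* The window is expanded to the peaks of the first and
  last beats and HR is `(n_peaks - 1) * 60 / span`. Counting intervals
  rather than peaks makes the estimator exact on a periodic train; a
  peak-count numerator over a peak-to-peak span would overestimate by one
  interval's worth.
* *FFT.* The window is zero-padded to 4096 points (bin ≈ 0.29 beats/min)
  and HR is the in-band power argmax.
* *AR dominant pole.* An order-8 autoregressive model is fitted by Burg's
  method (`stats::ar.burg`); among the poles whose angle maps into
  90–270 beats/min the largest-magnitude one gives the rate. Estimates are
  invalid when no in-band pole exists or the dominant pole magnitude is
  below 0.8 (a weak resonance carries no rate information).
* *AR best model.* Orders 6–12 are fitted; orders whose dominant in-band
  pole frequency agrees with the argmax of the model's frequency response
  to within 1 beat/min are candidates, and the candidate with the
  largest pole magnitude wins. With no candidates the estimate falls back
  to the order-8 response peak and carries a fallback flag.

All estimators return values inside 90–270 beats/min or an invalid flag.

**Kalman smoothing.** Estimates are smoothed by a scalar random-walk Kalman
filter: process variance `q = 4 (beats/min)^2` per second, measurement
variance `r / max(sqi, 0.05)^2` with `r = 4`, and measurements with
SQI < 0.3 treated as missing (prediction only, growing posterior variance).
All four constants are arguments.

## Respiratory chain

Twelve channels are extracted per frame: the three colour-channel PPGi
means; area, city-block perimeter (count of 4-adjacency skin/background
transitions) and centroid x/y of the whole skin label; and the major axis,
minor axis, orientation, eccentricity and area of the ellipse
moment-matched to the largest connected skin region. Ellipse axes are
`4 * sqrt(eigenvalue)` of the central second-moment matrix (with the 1/12
pixel-spread correction), which reproduces a disc's diameter to better
than 0.1 %. Each channel is filtered by a 100th-order high-pass FIR at
0.3 Hz and an 80th-order low-pass FIR at 2.0 Hz (18–120 breaths/min) and
analysed over 10 s windows sliding by 1 s.

Two independent detectors find breaths: crossings of the 2 s centred
mean-average curve (MAC), and the slope-sum transform with a 300 ms
upslope window (six samples at 20 Hz), both with a 500 ms refractory
period. When their window counts disagree the window SQI is 0; otherwise
it is the mean per-breath score (activity gate × range gate × DTW
similarity against a per-channel breath template). The per-channel rate is
interval counting over the breath-expanded window, as for HR.

**Fusion.** Each channel's 1 Hz series feeds its own Kalman filter
(range 18–120 breaths/min) and the fused value combines channel posteriors
with weights `sqi / posterior_variance`. The combination is the weighted
*median*, not the weighted mean: a minority of channels can lock onto a
harmonic of the true rate with internally consistent quality — in the
synthetic scenes the ellipse major axis does exactly this, because the
rasterised x-variance of a nearly axis-aligned ellipse is an even function
of the minor-axis modulation, so that channel oscillates at twice the
breathing rate with a clean waveform — and a mean is dragged several
breaths/min toward such a channel while the median follows the consensus.
The fused SQI is the weighted mean of channel SQIs.

## Reference vitals

The monitor's two independent heart-rate sources are gated by waveform
quality and mutual agreement: the ECG SQI is the F1 score of one-to-one
beat pairing (150 ms tolerance) between two structurally different QRS
detectors (slope-sum and derivative-threshold), and the PPG SQI is the mean
Pearson correlation of detected pulses against the window's average pulse,
clipped to [0, 1]. A second is valid when both SQIs exceed 0.5 and the two
rates differ by at most 5 beats/min (inclusive, following the monitoring
standard's error allowance); the reference is their mean.

For respiration, three ECG surrogates are derived at the detected R-peaks —
R-peak amplitude, respiratory sinus arrhythmia (60/inter-beat interval) and
the QRS area within ±50 ms — and spline-resampled to a 4 Hz grid (the
respiratory band tops out at 2 Hz, so 4 Hz satisfies Nyquist). Together
with the impedance pneumography waveform resampled to the same grid, each
signal yields a counting estimate and an order-8 AR dominant-pole estimate
(0.3–2.0 Hz band) over 20 s windows, gated by spectral purity (fraction of
band power within ±0.15 Hz of the dominant frequency, threshold 0.5). The
four per-signal series are fused per method with the same Kalman machinery;
a second is valid when both fused estimates exist and differ by strictly
less than 5 breaths/min, the value being their mean. Note the deliberate
asymmetry: the HR rule is inclusive at 5, the RR rule strict below 5.

## The synthetic scene generator

Clinical video of infants cannot be redistributed, so every stage is
validated on synthetic scenes with known ground truth. A scene renders a
skin-coloured filled ellipse (fixed light-skin RGB mean with a static
Gaussian per-pixel texture, standard deviation 6) on a darker background.
The green channel over the ellipse is modulated by
`1 + a * (sin(2*pi*phi) + 0.3 * sin(4*pi*phi))` at the cardiac phase —
a non-sinusoidal pulse with a distinct upslope for the slope-sum detector —
and the ellipse minor axis and vertical centroid are modulated at the
respiratory phase. Motion bursts translate the ellipse sinusoidally,
lighting steps scale all channels multiplicatively, absence intervals
render background only (and empty masks), and per-pixel Gaussian noise is
added per frame.

Two noise sources are distinguished deliberately. Independent per-pixel
noise averages out of a region mean over tens of thousands of pixels and
so contributes almost nothing to the PPGi noise floor. Real recordings also
carry a fluctuation *shared* by all pixels — ambient-light flicker and
camera gain variation — which survives spatial averaging unchanged; the
generator models it as a per-frame multiplicative brightness jitter
(`flicker_sd`, default 0.3 % of frame brightness, about a tenth of the
default pulse amplitude at the PPGi level). Without it the extracted PPGi
is an implausibly clean two-tone signal on which any spectral estimator's
behaviour is decided by numerical ties rather than by signal structure.

Default conditions: 20 frames/s, 160 × 120 px frames, pulse modulation
depth 0.03, shape modulation 0.03, pixel noise 1 intensity unit. Matched
monitor waveforms are generated from the same rate schedules: a 500 Hz ECG
whose Q/R/S template train is amplitude- and baseline-modulated at the
respiratory phase (so all three surrogates are recoverable), a 125 Hz PPG
with systolic peak and dicrotic notch placed at fractions of each beat
interval, a 64 Hz near-sinusoidal impedance trace, and 1 Hz numerics
computed from the event times. Identical configurations (including the
seed) reproduce scenes bit-exactly; per-frame noise uses seeds derived from
the scene seed and frame index, so frames can be evaluated lazily in any
order.

What the generator does not emulate: photorealistic infant appearance,
incubator optics, compression artefacts, segmentation errors (ground-truth
masks are geometrically exact), apnoea or bradycardia events, and infrared
night-time operation. Passing the end-to-end checks therefore demonstrates
that the estimators recover known rates through the full chain under
controlled disturbances — not clinical-grade accuracy on real video.

## Validation problem sizes

The package's end-to-end check runs a 10-minute stepped-rate scene
(HR 120→180 beats/min, RR 40→80 breaths/min at 300 s, two 20 s motion
bursts, one 1.3× lighting step, seed 42) at 160 × 120 resolution —
12 000 frames — and requires quiet-second MAE at most 2 beats/min for the
AR best-model estimator and at most 3 breaths/min for the fused
respiratory rate, plus a permutation test (p < 0.01) that motion-burst
window SQIs sit below quiet-window SQIs. Unit tests use 5–60 s scenes at
80 × 60. These sizes were chosen so the whole suite runs comfortably on a
single CPU while the long scene still spans both schedule steps and all
disturbance types.

## Known limitations

* At 20 Hz sampling, beats above ≈240 beats/min approach the refractory
  quantisation limit (a 264 beats/min train is 4.5 samples per beat) and
  the slope-sum detector under-counts; the spectral estimators are
  unaffected.
* The first pulse harmonic falls inside the cardiac band when HR is below
  135 beats/min. The best-model candidate rule and the noise floor keep
  the AR estimators on the fundamental in realistic conditions, but on
  noise-free tonal signals the dominant-pole method can select the
  harmonic.
* The breath detectors cannot resolve rates at the very top of the
  18–120 breaths/min range: at 120 breaths/min the breath period equals
  the 500 ms refractory period.
* The weighted-median fusion needs a majority of channels on the true
  rate; if most channels lock onto a harmonic simultaneously the fused
  value follows them.
* `evaluate_vitals` reports pooled Pearson correlation over valid seconds;
  per-session averaging, when sessions exist, is the caller's
  responsibility.
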