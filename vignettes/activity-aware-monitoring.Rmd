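---
title: "Activity-aware vital-sign monitoring: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Activity-aware vital-sign monitoring: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(activital)
```

## The problem

Vital-sign thresholds are meaningless without knowing what the wearer is
doing: a heart rate of 150 bpm is unremarkable while running and alarming
while lying down. `activital` implements an activity-conditional
monitoring pipeline for a wireless body-area network of three triaxial
accelerometers (chest, wrist, ankle) and a single-lead chest ECG, all
sampled at 50 Hz:

1. **Vital-sign extraction** — heart rate (HR) from ECG R peaks on 4 s
   windows, breathing rate (BR) from the ECG-derived respiration (EDR)
   tachogram on 20 s windows with 80% overlap.
2. **Activity recognition** — eight activities of daily living
   (standing, sitting, lying, walking, climbing stairs, cycling,
   jogging, running) via a two-layer classifier: a decision tree gates
   the activity *intensity* on 1 s magnitude windows, then an
   intensity-specific random forest fuses the two most informative
   sensors.
3. **Zone learning** — per (vital, activity) green / yellow / red ranges
   from cohort measurements by a five-bin histogram rule.
4. **Alerting** — a graded escalation protocol over the zones of the
   monitored vitals.

A synthetic-data generator with known ground truth makes every stage
testable without external recordings.

## Vital-sign extraction

### Baseline filtering

The ECG is filtered with a second-order IIR notch, center 0.05 Hz,
quality factor 0.005 (the bandwidth is `f0 / Q`). With so low a center
and Q this is not a narrow notch in the usual sense: its pole pair sits
extremely close to the unit circle near DC, so over any practical record
the filter suppresses the mean and slow baseline wander (gain ~0.02 at
0.2 Hz) while the upper ECG band passes (gain ~0.97 at 20 Hz). The
mid-band is partially attenuated (~0.7 at 10 Hz); this is harmless for
peak detection, which thresholds against a local rolling mean rather
than absolute amplitude. The coefficient formulation matches the common
scientific-Python notch designer, and the unit tests pin the
coefficients to values computed independently with it.

### R-peak detection

Within each 4 s window the signal is shifted to a nonnegative baseline
and compared against a centered 0.25 s-half-width rolling mean raised by
20% — the raise is the standard guard that keeps flat or noisy segments
from producing spurious regions of interest. Each maximal run above the
threshold yields one peak at its maximum (first index on ties).

At 50 Hz one sample is 20 ms, which is coarse relative to the
few-percent respiratory modulation of RR intervals, so each peak time is
refined by 4x cubic-spline up-sampling around the detected maximum
(5 ms resolution). RR intervals come from the refined times; the window
mean maps to HR via `round(60000 / mean(rr_ms))`. Windows with HR above
190 bpm are flagged `bad_signal` (a simple quality index — such rates
during daily activity are overwhelmingly motion artifact) and excluded
from zone learning and alerting.

Peaks are cached across windows; a pulse straddling a window boundary is
seen by both windows, so cache entries closer than a 200 ms refractory
period are merged (no true RR interval can be shorter, because RR
sequences implying more than 300 bpm are rejected at generation).

### Breathing rate (EDR)

The instantaneous HR of each RR interval, placed at the later peak's
time, is cubic-spline interpolated onto a uniform 4 Hz grid — the
standard low-rate tachogram resampling. The waveform is then band
limited with a zero-phase second-order low-pass at 0.7 Hz, comfortably
above any plausible breathing rate, to remove beat-quantization ripple.

Respiratory peaks are local maxima separated by at least 1 s whose
*topographic prominence* exceeds `max(1.5 bpm, 10%)` of the half
peak-to-peak range. The absolute floor is derived, not tuned by eye:
residual quantization ripple after band limiting stays below roughly
`HR^2 / 12000 * 0.5` bpm (about 1.2 bpm at 180 bpm), while the weakest
genuine respiratory crest (4% modulation depth at 50 bpm, attenuated by
spline undersampling) still carries about 2.5 bpm of prominence, so any
floor in between separates the two populations; 1.5 bpm is the midpoint
of the safe region. BR is the plain count estimator
`n_peaks / 20 s`, reported as `round(60 * f)` brpm. Crest detection runs
on a grid extended 2 s beyond the window (supported by real beats from
outside the span) and counts only crests inside the half-open
`[start, start + 20)` — this makes the count unbiased at window
boundaries; without it the 4 s stride is phase-locked with ~2 s breath
periods and systematically loses one crest per window near 0.5 Hz.

**Validity envelope.** The tachogram samples respiration once per beat.
Breathing faster than about a third of the beat rate cannot be recovered
by any RSA-based EDR method (near half the beat rate it aliases
outright). The synthetic recovery fixtures therefore draw BR jointly
with HR, uniform on `[0.1, min(0.5, hr/180)]` Hz. Within this envelope
the package recovers HR within ±2 bpm and BR within ±2 brpm of ground
truth on clean fixtures; outside it no estimator of this family can.

Note also the estimator's intrinsic granularity: a count over 20 s
resolves BR in steps of 3 brpm; the per-fixture recovery error is
assessed against the window-mean over a 60 s record, which averages the
quantization down.

## Activity recognition

### Features

From each 2 s window the time-domain vector holds 12 statistics per axis
(mean, standard deviation, min, max, median absolute deviation,
interquartile range, variance, zero crossings, root-mean-square,
skewness, kurtosis, energy), the signal magnitude area (SMA) and the
three pairwise axis correlations — 40 attributes for the raw triaxial
signal, 13 for the magnitude signal. Frequency-domain vectors apply the
same 12 statistics to the one-sided FFT magnitude spectrum (DC removed)
plus spectral entropy and the index of the spectral maximum. Six
variants (`xyz_t`, `xyz_f`, `xyz_tf`, `mag_t`, `mag_f`, `mag_tf`) are
available.

Statistical conventions the source method leaves open, fixed here and
asserted in tests: `mad` is the unscaled median absolute deviation about
the median; `iqr` uses linearly interpolated quantiles; `zc` counts
strict sign changes of the mean-centered signal (zero-crossing about the
mean, not about zero, so a gravity offset does not saturate the
feature); skewness is adjusted Fisher–Pearson and kurtosis excess
Fisher, both defined as 0 for a constant signal; energy is the mean of
squares, so `energy = rms^2` exactly; SMA uses absolute values (the
literal signed sum is available via `sma_absolute = FALSE`); correlation
with a zero-variance axis (a noiseless posture) is defined as 0.

Backward elimination ranks features by random-forest impurity
importance and removes the weakest *unit* per step; on raw triaxial
vectors the per-axis triple of a statistic is scored by its mean
importance and removed as a unit, so the three axes of one statistic
never straddle the cut.

### Two-layer fusion

Layer 1 is a CART decision tree over exactly four magnitude features
(mad, var, rms, iqr) of 1 s windows, predicting intensity bands defined
by MET score: light (< 3), moderate (3–6), vigorous (> 6). For a 2 s
analysis window the gate classifies both 1 s halves; a split vote
resolves to the more vigorous class — conservative for alerting, since
treating vigorous activity as light would flag exercise-elevated vitals
as emergencies, whereas the reverse merely widens the accepted range.

Layer 2 trains one random forest per intensity band over the early
(feature-level) fusion of two sensors — ten attributes per sensor
(mean, std, rms per axis, plus SMA), twenty per fused vector. The pairs
are fixed rules: light fuses chest + wrist, moderate wrist + ankle,
vigorous chest + ankle. The chest sensor gates by default (any placement
gates acceptably; this is configurable). If a sensor drops out, models
trained with `all_pairs = TRUE` allow rerouting to the best available
pair, and the fallback is reported per window.

WEKA's J48 and random forest are replaced by `rpart` and `ranger` with
fixed seeds and default parameters; exact behavior of the original
implementations is not reproduced, and no claim depends on it.

Evaluation offers stratified k-fold (subject-dependent, optimistic) and
leave-one-subject-out (LOSO; the held-out subject never appears in
training, audited by a hard assertion in the fold runner). Metrics are
per-class accuracy (= recall), precision, recall and F-measure from the
pooled confusion matrix.

## Zone learning

For one (vital, activity), the integer measurements' range `[min, max]`
is split into five equal-width bins (half-open, last closed). Bins with
counts strictly above the mean count are green; equality is *not* green
(the rule demands "higher than"), and when no bin exceeds the mean — a
uniform histogram — the maximum-count bins are green, which guarantees a
non-empty normal range. A single non-green bin strictly between two
green bins is promoted. If disjoint green segments remain, the widest
(first on ties) is kept; the procedure presumes a unimodal histogram and
this is the least surprising repair. The green range runs between the
bin *edges* (rounded to integers) of the first and last green bin;
yellow ranges fill out to the observed extremes with ±1 adjacency; red
is everything outside the observed range. Degenerate input (all values
equal) yields a point green range and no yellow.

HR boundaries are snapped to the nearest multiple of 5 (ties away from
zero), reflecting the ±3 bpm accuracy of commercial monitors; adjacency
is re-established afterwards and the operation is idempotent. BR
boundaries are untouched.

Zones are serialized as JSON and rendered as IF–THEN rules
(`IF activity=walking THEN normal HR range is 70–125 bpm`); the
emergency rule prints both open sides.

## Alerting

Given the current activity (the label covering the measurement window's
midpoint) each measurement is classified into its zone. Per 4 s
evaluation tick: two reds alert the emergency service, one red alerts
the caretaker, two yellows alert the user, one yellow warns the user,
all green is silent. Red dominates yellow (single message per tick,
highest severity); severity is monotone in every vital's zone, a
property the tests check over random zone vectors. `bad_signal`
measurements and measurements without a fitted zone entry or covering
activity are held, never alerted.

## The synthetic generator

Accelerometry: postures are a constant 9.80665 m/s² gravity vector in a
posture-specific orientation plus Gaussian noise; locomotion adds a
sinusoid along the gravity axis (plus a half-amplitude quadrature
component) at profile-specific frequency and amplitude, ordered walking
< stairs < cycling < jogging < running. The exact frequencies and
amplitudes are configuration, not claims about human gait. Cohort
simulation draws per-subject offsets once (gravity tilt of ~4° SD,
log-normal amplitude scale of ~5%) and applies fixed per-placement frame
rotations and amplitude multipliers (wrist and ankle move more than the
chest).

ECG: one Gaussian pulse (SD 12 ms) per beat — sufficient for a
rolling-mean detector, with no P/T morphology. Respiration modulates
both the RR interval (4% depth, the RSA route consumed downstream) and
the pulse amplitude (20%, present for realism only). Optional baseline
drift and noise are available. Cohort ECG assigns each activity an
MET-graded heart rate (`55 + 12.5 * MET` bpm, subject offset SD 4 bpm)
and breathing rate (`(9 + 2.6 * MET) / 60` Hz), so learned zones are
genuinely activity-conditional.

What the generator does *not* emulate — and what passing tests therefore
do not establish about real recordings: motion artifacts in the ECG,
electrode noise, non-sinusoidal gait harmonics, within-activity
nonstationarity, sensor drift, and transitions mid-window. The MHEALTH
reproduction mode (`reproduce_mhealth()`, requiring a local copy of the
public dataset) exists precisely to confront the pipeline with real
data; it prints its figures next to the published reference values
without asserting them.

## Determinism and problem sizes

Every stochastic operation runs under a private RNG seeded explicitly;
no call touches the global RNG state. Derived sub-seeds stay below
2^31. The test-suite and acceptance problem sizes — 10 subjects × 8
activities × 30 s for the LOSO benchmark (1,200 windows), 50 ECG
fixtures of 60 s for vital recovery, 1,000 random sample sets for the
zoning oracle — were chosen as the smallest sizes at which the
quantities of interest are stable across seeds.

## Known limitations

* BR is count-quantized to 3 brpm per 20 s window; clinical use would
  average or lengthen windows.
* The EDR validity envelope excludes breathing above ~1/3 of the beat
  rate; tachypnea during bradycardia is invisible to this estimator.
* Zones need ≥ 5 quality measurements per (vital, activity); sparse
  activities are skipped rather than extrapolated.
* The alert protocol evaluates each tick independently; elevated vitals
  carried over from a just-finished vigorous activity will warn until
  the zones of the new activity apply.
* Demographic cohort selection is an explicit row filter; no similarity
  matching is provided.
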