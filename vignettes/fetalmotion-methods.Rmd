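---
title: "Detecting gross fetal movement in overnight accelerometry: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting gross fetal movement in overnight accelerometry}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fetalmotion)
```

## The measurement problem

Two capacitive acceleration sensors record overnight: one on the maternal
abdomen (FM channel, high sensitivity) and one on the thigh (MM channel,
about one sixth the sensitivity). Gross fetal movements appear on the FM
channel as irregular bursts of 0.5–3 s. Everything else on that channel is
an artifact to remove: the ~1.0 Hz maternal heartbeat, respiration at 3–5-s
breath intervals (irregular and burst-like during REM sleep), maternal body
movements (which also appear on the thigh sensor), periodic limb movements
(PLM), and fetal hiccups — rhythmic ~2-s-period movements that are
physiologically distinct from gross movement and would inflate counts by
roughly a third if included. The output of interest is the count of gross
fetal movements per hour of *analysis time* (recording time minus wake,
restroom and filter-transient exclusions).

## Pipeline and parameters

### Filtering

Both channels pass a 0.5 Hz high-pass (first order, −6 dB/oct) and a 2.5 Hz
low-pass (second order, −12 dB/oct); a 1.0 Hz notch (−3 dB bandwidth 0.2 Hz)
removes heartbeat on both channels, and a 0.3 Hz notch (bandwidth 0.1 Hz)
removes respiration on the FM channel only. Note that the respiration notch
sits *below* the high-pass corner: both act on the slow respiratory
component, and the pair is retained as published.

The filter family is not dictated by the stated roll-offs alone; we use
bilinear-transform Butterworth designs of exactly the stated orders and
constrained biquad notches, the simplest designs matching −6 and −12 dB/oct.
Filters are applied forward–backward by default (`zero_phase = TRUE`), so
FM and MM event timings stay aligned for cross-channel masking; this doubles
the effective roll-off, which we accept and verify spectrally in the tests
(measured: ≤ −20 dB at both notch frequencies, ≤ −15 dB at 0.05 Hz, ≥ −3 dB
at 1.8 Hz). A causal single-pass mode is available for streaming use. The
first and last 10 s (`edge_transient_s`) are treated as filter transients:
events there are rejected and the time is excluded from analysis time.

### Detection

The filtered signal is rectified and summed into 50-ms bins (`bin_ms`). A
bin is supra-threshold when its integral exceeds `ratio_threshold` (2.0,
"200 %") times the mean of bins in the surrounding ±3 s
(`baseline_window_s`), the bin itself excluded and windows truncated at the
series edges, *and* is at least the fixed channel minimum
(`min_integral_fm = 15`, `min_integral_mm = 20` device units). Runs of
supra-threshold bins with gaps ≤ `merge_gap_s` (0.25 s) merge into one
event.

Design choices that the published description leaves open, fixed here:

* "higher than twice" is read strictly (`>`), and the comparison is made on
  integral values, not raw amplitudes.
* The baseline is the raw local mean, not an event-censored one — a single
  pass, matching the described procedure. A limitation follows: a
  sustained continuous movement raises its own baseline and can partially
  self-suppress.
* A silent baseline is floored at machine epsilon, so on silent stretches
  the ratio rule passes and the channel minimum alone decides.
* Sub-minimum bins produce *no* event (rather than a rejected one); the
  supported way to inspect sub-threshold signal is re-running detection
  with the minima set to 0, which is exactly what the QC loop does.

Why this rejects the heartbeat: after filtering, a constant-amplitude
heartbeat is a near-continuous rectified oscillation, so each beat's ±3-s
baseline is filled with ~6 identical beats and the peak-to-mean ratio is
about π/2 ≈ 1.57 < 2. A *sparse* spike train would not self-suppress — the
regularity *and* duty cycle matter, which is why the simulator models the
heartbeat as contiguous biphasic beat cycles rather than isolated spikes.

### Artifact rejection

Applied in fixed precedence (first applicable reason wins, a rejected event
is never relabeled): wake/restroom → maternal movement → PLM → hiccup.

* **Wake / restroom.** A fixed clock minute with ≥ 4 accepted MM events
  (`wake_events_per_minute`) is wake; brief awakenings below that are kept.
  Maximal wake runs ≥ 300 s (`restroom_min_duration_s`) are relabeled
  restroom. Both are removed from analysis time and their FM events
  rejected. The per-minute reading of "fewer than four times in one minute"
  is the only one computable from the recorded channels; fixed clock
  minutes (not sliding windows) keep the rule deterministic. Restroom
  detection itself is not specified beyond "longer", hence the duration
  criterion, configurable.
* **Maternal movement.** FM events intersecting any accepted MM event
  dilated by ±1 s (`mm_guard_s`) are rejected.
* **PLM.** MM events of 1–5 s (`plm$min_duration_s` = 1.0) in maximal
  series of ≥ 4 with onset-to-onset intervals of 5–90 s, following the
  standard sleep-scoring series convention for the minimum run length.
  Because PLM members are themselves MM events and the guards are equal,
  the maternal-movement rule usually claims these FM events first; the PLM
  detector remains independently exposed (and is the component that makes
  the *train* structure explicit). Note a ~1-s jerk whose envelope tapers
  can be measured slightly short by supra-threshold extent and drop out of
  a run — detection-boundary shaving that mirrors the marginality of the
  1.0-s criterion on real data.
* **Hiccups.** Accepted FM events ≥ 0.2 s (`hiccup$min_event_duration_s`)
  count as candidates; minutes with > 15 (`events_per_minute_threshold`)
  are hiccup minutes, maximal runs of which form bouts. All FM events in a
  bout are rejected, but the bout's time stays in the analysis denominator
  — the exclusion is of *events*, the description does not reduce recording
  time for hiccups. Trailing/leading bout minutes below the threshold are
  not excluded, so a burst inside a bout's boundary minute can be excluded
  with it (minute granularity), and sub-threshold hiccup tails can survive
  — both acknowledged limitations of the published rule.

### Diagnostics

Onset-to-onset intervals of accepted FM events are binned at 1 s over
0–40 s plus an overflow bin. "Extremely high" 3–5-s columns (respiration)
or 2-s column (hiccups) are made operational as: band mass >
`flag_factor` (3) × the median of non-zero bins *outside* the band, with a
minimum band mass of `flag_min_count` (20). The exclusion of the tested
band from the reference median is deliberate: a histogram whose entire mass
sits in one suspect column must flag, and a uniform histogram must not.
Onset-to-onset (not end-to-onset) intervals are used because the ~2-s
hiccup signature is a rhythm period.

### Epochs, agreement, longitudinal statistics

Epoch `[10k, 10k+10)` is labeled 1 if any accepted FM event intersects it;
epochs touching wake/restroom/edge intervals are dropped whole (no
truncation). PABAK = 2·p₀ − 1 with p₀ the agreement proportion over epochs
kept by both raters; Cohen's κ is reported from the 2×2 table (defined as
p₀ in the degenerate pe = 1 case); Landis–Koch labels use upper-inclusive
intervals with 0 assigned to "poor". Aggregates use the sample SD (n − 1),
which reproduces the printed "0.83 (0.04)" from the six per-subject means —
note the exact mean is 0.835, whose IEEE double sits just below the decimal
midpoint and therefore prints "0.83" under `%.2f`.

The repeated-measures ANOVA is the classical balanced decomposition
SS_total = SS_subjects + SS_conditions + SS_error with
F = MS_cond/MS_error on (s−1, (s−1)(n−1)) df; a zero error mean square
reports F = Inf with a note rather than NaN. Incomplete tables are refused
by default with an explicit complete-case option and no imputation (the
reference analysis reached (3, 33) df with 12 subjects despite missing
sessions by means it does not describe; we do not guess). Scheffé contrasts
use the ANOVA's MS_error: F_contrast = n·diff²/(2·MS_error), significant
when ≥ (s−1)·F_crit(α; s−1, df_error), never more liberal than the
unadjusted paired contrast.

## The simulator: what it emulates, and what a green test establishes

No recordings are deposited with the reference description, so the
generator (`sim_config()`, `simulate_recording()`, `scenario_library()`)
produces the *statistical structure* of each signal class with exhaustive
ground-truth annotations:

* fetal bursts: Hann-enveloped sinusoids, carrier drawn from the 0.5–2.5 Hz
  passband, 0.5–3 s, ~100/h;
* heartbeat: contiguous biphasic ~1.0 Hz beat cycles with small period
  jitter (a *regular* integral envelope, see above);
* respiration: a slow quasi-sinusoid at 3–5-s breath periods plus, during
  REM episodes (by default 60 % of the final third of the night, where REM
  dominates), a small breath-locked transient — this is the component that
  leaks into detection when the minimum thresholds are lifted;
* maternal movements and PLM jerks: flat-top (tapered-cosine) envelopes —
  abrupt-onset muscle activity — on the MM channel with crosstalk onto the
  FM channel at `crosstalk_gain × fm_mm_gain` (0.3 × 6);
* hiccup bouts: 0.35-s biphasic pulses at 2 ± 0.15 s periods for 5–15 min;
* wake/restroom: MM-event clusters at 6 and 8 events/min for 1–3 min and
  5.5–8 min respectively;
* white noise floor (SD 1 device unit) on both channels.

Device units are arbitrary (the hardware's ADC scaling is unpublished); the
calibration is chosen once so the default minima 15/20 sit between the
noise-floor integrals (≈ 1) and typical burst integrals (≈ 50–150), and so
respiration transients integrate below 15 while remaining well above the
noise — i.e. the minima are *meaningful* in the simulated world exactly as
described for the real one. Scenario durations default to one hour (rates
are per-hour, so statistics scale); a real night is 6–9 h.

Not emulated: genuine cardioballistic waveform shape, respiratory-cardiac
coupling, sensor detachment, obesity-related apnea artifacts, anterior
placenta attenuation. A green simulator test therefore establishes that the
*rules* behave as specified on signals with the described timing and
amplitude structure — not clinical sensitivity on real recordings, which
requires the original validation design (manual/ultrasound comparison).

## Numerical conventions

All intervals are half-open `[start, end)` in seconds from recording start;
event boundaries are bin-aligned. CSV round trips write numerics with
`%.17g` and are bit-identical. The pipeline contains no randomness — two
runs on the same input and config produce byte-identical outputs; all
simulator randomness flows from one integer seed and restores the caller's
RNG state. A recording must be at least `10 / highpass_hz` s (20 s at the
default corner) for transients to fit; sampling rates down to 20 Hz are
accepted (integral bins floor their boundaries when samples-per-bin is not
an integer).

## Known limitations

* Single-pass baseline: long continuous fetal activity partially raises its
  own threshold (documented above).
* The 1.0 Hz heartbeat notch is fixed; a maternal heart rate far from
  60 bpm relies entirely on the adaptive ratio's self-suppression.
* Minute-granularity wake and hiccup rules create boundary effects at
  episode edges.
* The ANOVA handles complete balanced tables only, by design.
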