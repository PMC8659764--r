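---
title: "Methods: from a smart-glove recording to an overnight sleep report"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from a smart-glove recording to an overnight sleep report}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

sleepglove analyzes overnight recordings from a finger-worn pulse-oximeter
glove that acquires three channels: a photoplethysmogram (PPG) at 100 Hz,
peripheral oxygen saturation (SpO2) at 1 Hz, and a movement channel derived
from a 50 Hz 3-axis accelerometer. From these it produces a per-minute sleep
report: heart rate with bradycardia/tachycardia and AF/PVC-like irregularity
flags, breathing rate, apnea/hypopnea events with obstructive/central subtype
classification, and movement-based sleep stages. This vignette is the
package's account of each method, its assumptions, and the choices made where
the design was genuinely open.

```{r setup, eval = FALSE}
library(sleepglove)
```

## The block codec

The device stores data in 4 KB flash blocks of 25 rows x 157 bytes, using a
prefix-free (empirical Huffman) code over six symbols: delta differences
(DD, descriptor `0`, 8-bit signed), garbage (GB, `10`), absolute values (AV,
`110`, 18 bits), scale factors (SF, `1110`, 3 bits), SpO2 (`11110`, 6 bits)
and movement counts (`111110`, 16 bits). `FORMAT.md` gives the full wire
grammar with a worked hex example. Four points deserve explanation because
the hardware description leaves them open:

* **SF is exact, never rounding.** A delta too large for 8 bits is stored as
  a scale code plus quotient only when a scale in {2, 4, ..., 256} divides it
  exactly with an 8-bit quotient; otherwise the sample is re-sent as an
  18-bit absolute value. Any rounding rule would contradict the codec's
  lossless contract, which the round-trip property tests enforce bit by bit.
* **Row layout.** Only row 1 carries the 4-byte sample counter; rows 2-25
  carry just their 2-byte useful-bit count. 25 x 157 = 3925 bytes, padded
  with zeros to the 4096-byte flash block.
* **Auxiliary timestamping.** SpO2 and movement tokens are stamped at the
  most recent preceding PPG sample, preserving the 1 Hz SpO2 cadence exactly
  through an encode/decode cycle.
* **Garbage granularity.** Artifact samples (outside the 18-bit range)
  become GB tokens - the sample counter advances, the value is lost, and the
  encoder resynchronizes with an AV. On decode, the whole enclosing block is
  flagged invalid for analysis; downstream modules treat those samples as
  missing. This is the only sanctioned loss.

Blocks arrive in flash order, not time order, so the decoder sorts by sample
counter, rejects blocks whose 8-bit XOR checksum fails (recording a gap),
and keeps the first of any duplicated counter. For a clean 8-hour night
nearly every sample is a 9-bit DD token, giving roughly 3.5 MB per night -
comfortably inside the ~5 MB the transport design assumes.

## Pulse detection and heart-rate analytics

The PPG is z-score normalized, then pulses are detected as local maxima with
a minimum topographic prominence. Prominence is the natural criterion here
because the PPG's dicrotic notch is a genuine local maximum that must not be
counted as a beat; its prominence is bounded by the notch-to-saddle depth,
well below a full pulse. Defaults: prominence 0.8 (on the z-scored signal,
suppressing dicrotic notches up to half the pulse amplitude) and a 300 ms
refractory period. The hardware papers fix the prominence "empirically"
without printing a value, so it is a config parameter. Peak positions are
refined to sub-sample precision with a three-point parabola; without this,
every interval carries +/-10 ms quantization jitter at 100 Hz, which matters
because the irregularity rules operate on a 50 ms margin.

Per one-minute window:

* **Heart rate** is `60000 / mean(IPI)` over the minute's intervals, after
  ectopic cleaning: intervals deviating more than 30 % from the running
  median of five are masked and linearly interpolated *for averaging only*.
  The raw intervals are kept for the irregularity rules, which must see the
  ectopy they are looking for.
* **Bradycardia**: mean inter-pulse interval > 1200 ms (HR < 50 bpm);
  **tachycardia**: mean interval < 500 ms (HR > 120 bpm). Strict
  inequalities. The averaging interpretation of "episode" follows the
  device's per-minute IPI averaging; a single-interval rule is available via
  `episode_rule = "any"`.
* **AF / PVC**: with `m` the minute's mean interval, any interval more than
  50 ms above `m` flags possible atrial fibrillation, more than 50 ms below
  flags a possible premature ventricular contraction; one detection labels
  the minute. The deviation is measured against the minute mean (the rule's
  "average threshold"); a consecutive-difference variant sits behind
  `af_pvc_rule = "successive"`.

A real limitation worth stating: the 50 ms rule is sensitive to any rhythm
whose natural swing approaches 50 ms. Healthy respiratory sinus arrhythmia
of +/-4 % at 60 bpm already swings +/-40 ms, so minutes adjacent to events,
stage transitions, or rate changes can be flagged. This is a property of the
rule, not of the implementation.

## Breathing rate

Respiration modulates the PPG three ways: baseline wander (respiratory-
induced intensity variation, RIIV), pulse amplitude (RIAV) and pulse timing
(RIFV, respiratory sinus arrhythmia). The package extracts all three -
per-pulse peak-to-trough amplitudes, inter-pulse intervals, and the < 0.5 Hz
PPG baseline - and cubic-interpolates them to a uniform 4 Hz grid. Per
window (32 s or 64 s; 64 s default, 50 % hop), each modulation's Welch
spectrum (Hann window, 50 % segment overlap, zero-padded FFT) is searched in
the respiratory band 4-60 breaths/min; the dominant peak gives a
breathing-rate reading and the fraction of in-band power within one spectral
main lobe of that peak gives a quality index in [0, 1]. Readings below the
quality floor (0.2) are discarded - white-noise-like modulations produce no
estimate rather than a random one.

The per-window readings are fused with a Kalman smoother: a scalar
random-walk state (the breathing rate; process s.d. 0.5 bpm per window
step), one measurement per surviving modulation with variance
`(2 bpm)^2 / quality`, a forward filter and a Rauch-Tung-Striebel backward
pass. Inverse-variance weighting means a modulation whose quality collapses
simply stops influencing the track. The state-space of the original
fusion method is not published, so these are the package's own minimal
choices, all exposed in `respiration_config()`.

On clean synthetic nights with piecewise-constant rates in 8-25 breaths/min,
the fused 64 s estimate recovers the truth with a median absolute error well
under 1 bpm, and 32 s windows are never better than 64 s ones - the ordering
the original validation reported. Two protocol details in how the suite
scores this: windows straddling a rate change have no single true value and
are excluded, and the error is measured on the smoothed (fused) track, so
the 32-vs-64 gap is smaller than raw per-window spectra would show.

## Sleep-disordered breathing

The detection primitive is a **decrease in amplitude fluctuation (DAP)** of
the PPG: the per-pulse amplitude envelope (interpolated to 4 Hz) falling
below `1 - depth_threshold` times its 150 s running-median baseline for at
least 10 s, with events closer than 5 s merged. The detector reference that
fixes these numbers in the source system is not reproduced in the platform
description, so depth 0.3, duration 10 s and merge gap 5 s are documented,
config-exposed defaults.

A DAP becomes **apneic/hypopneic** only when an SpO2 desaturation onset
falls in a 20 s window opening at the DAP onset ("left-centered"); otherwise
it is a control event. Desaturations are drops of at least 3 percentage
points below the preceding 120 s median (a scoring-manual-style criterion;
the magnitude is config-exposed because the source leaves it to its
reference). Removing every desaturation therefore forces all DAPs to control
- this gating is the detector's specificity mechanism and is asserted as an
acceptance property.

For subtype classification, each event yields **37 features** from a 65 s
PPG window centered on it plus the SpO2 descent: 10 pulse-rate-variability
time-domain statistics, 12 spectral quantities over the LF (0.04-0.15 Hz)
and HF (0.15-0.4 Hz) bands - including the LF/HF sympathovagal balance and
pre/post-event heart-rate contrasts that capture the arousal surge - 8 DAP
morphology descriptors and 7 SpO2 descent statistics (`sdb_feature_names()`
is the registry; the original feature list is not printed, so this set is a
documented reconstruction). Undefined ratios carry a -1 sentinel rather than
NaN so vectors stay fixed-length and finite.

Classification uses a support-vector machine with Gaussian kernel
`K(x,y) = exp(-||x-y||^2 / 0.56^2)` (libsvm `gamma = 1/0.56^2`), classes
balanced by downsampling to the minority count, 10-fold cross-validation
stratified by class. Two numerical points:

* A 0.56-scale kernel on 37 standardized features is unusable: squared
  distances concentrate near `2 x 37`, all kernel values vanish and CV
  accuracy collapses to chance. The pipeline therefore ranks features by the
  absolute two-sample t statistic and keeps the strongest 10 before
  training - the dimensionality-reduction step the source procedure itself
  prescribes. With it, the synthetic obstructive-vs-central task is
  separated reliably; without it, not at all.
* Folds are stratified because unstratified folds on small balanced sets
  bias shuffled-label accuracy visibly below 0.5 (the held-out fold's
  majority class is the training fold's minority).

## Sleep stages

Every accelerometer step (20 ms) yields a movement derivative
`D = (|dx| + |dy| + |dz|) / delta`. The printed form of this expression in
the hardware description lacks the absolute-value bars, but a plain sum
telescopes to zero over any closed movement; magnitudes require the absolute
differences. A movement is counted at each upward crossing of the threshold
(25 units/s by default - above sensor noise at s.d. 0.01 units, below any
burst with per-axis steps of 0.5 units; the value is hardware-dependent and
config-exposed). Counting crossings rather than samples above threshold
makes a sustained excursion one movement, not fifty.

With `N_j` the count in minute `j` and `mN`, `sN` the whole-night mean and
sample standard deviation (computed only after the recording ends), the
stage rule is: Awake if `N_j > mN + 3 sN`, Light Sleep if `N_j > mN + sN`,
else Deep Sleep. Strict inequalities, so a night of identical counts is all
Deep Sleep, and labels are invariant under positive scaling of the counts.
Two arithmetic consequences the tests pin down: with the sample s.d., a
single outlier among `n <= 10` minutes can never reach Awake (its z-score is
bounded by `(n-1)/sqrt(n) <= 3`), and because the thresholds are relative,
a night with many wake minutes can never label any of them Awake - the rule
is designed for nights that are mostly sleep.

## The synthetic generator

`night_scenario()` / `generate_night()` produce the study conditions every
test consumes; nothing in the test suite downloads anything. The generator
emulates exactly the statistical structure the analyses assume:

* PPG at 100 Hz from a template pulse (Gaussian systolic peak, dicrotic
  notch at 40 % amplitude) placed at interval-driven times; respiratory
  amplitude (25 %), timing (3 %) and baseline-wander (15 %) modulations at
  the breathing-rate profile; additive Gaussian noise (1 % of pulse
  amplitude); integer quantization to the 18-bit range with a gain (800
  units) chosen so clean-night deltas fit signed 8 bits, as the transport
  design assumes.
* DAP events scale the amplitude by `1 - depth` (apnea 0.6, hypopnea 0.3,
  control 0.5 by default). Central events suspend the respiratory
  modulations (breathing stops); obstructive events append a 20 s post-event
  surge with intervals shortened 15 % - a deliberately simple, recoverable
  surrogate of the sympathovagal arousal that distinguishes the subtypes,
  with no claim of physiological waveform fidelity.
* SpO2 at 97 % baseline with coupled desaturations (5 points for apneas, 3
  for hypopneas) lagged 5-10 s with a 6 s descent, so the criterion depth is
  reached within the physiologic 20 s coupling window.
* Arrhythmic minutes: bradycardic (1300 ms intervals), tachycardic (450 ms),
  AF-like (every 4th interval +150 ms) and PVC-like (every 8th -150 ms);
  respiratory timing modulation is suspended in these minutes, as rhythm
  irregularity replaces sinus arrhythmia.
* Accelerometer noise (s.d. 0.01) plus movement bursts at 0/2/8 per minute
  for intended deep/light/awake minutes.

What the generator does *not* emulate - and hence what passing tests do not
show about real data: realistic pulse morphology variation, motion artifacts
that deform rather than erase pulses, SpO2 sensor dropouts correlated with
movement, apneas without desaturation, and inter-subject variability. The
parameter-recovery suite demonstrates that the implementations compute what
they claim under known conditions, not clinical performance.

Two known boundary effects, both inherited from taking the documented
defaults at face value: a hypopnea surrogate of depth 0.3 sits exactly at
the DAP detector's 0.3 depth threshold (after estimator bias the measured
decrease is ~27 %), so synthetic hypopneas are borderline-undetectable -
the detector-recovery suite uses depth-0.5 events; and below a depth
threshold of ~0.25 the generator's own 25 % amplitude modulation crosses the
threshold every breath, so raw DAP counts are only monotone in the threshold
across the detector's operating range (0.3-0.75 in the tests).

## The pipeline and report tables

`run_night()` decodes (if needed) and runs the six analyses in the
platform's order, then writes two tables whose field names mirror the
deployed system's SQL schema: per-minute `SleepEvents` (UserId,
EventStartDate, HeartRate, BreathingRate, OxygenSaturation, IsApnea,
ApneaType, IsPrematureVentricularContraction, IsAtrialFibrillation,
IsBradycardia, IsTachycardia) and one-row `NightSleepSummary` (stage
durations, counters, overnight means). Counters count flagged minutes,
except `ApneaCounter`, which counts detected apneic/hypopneic events (the
minute-flag count is reported alongside as `apnea_minute_count`);
`WakeUpsCounter` is the number of maximal runs of Awake minutes. Gaps from
corrupted or garbage blocks propagate as null minutes and are excluded from
the summary means. Outputs (CSV + JSON report + run log) are written
atomically; re-running on the same input is bit-identical.

Problem sizes used by the shipped test suite: codec properties on 1000
randomized short streams; an 8-hour night for the file-size bound and the
pipeline consistency/idempotence checks; a 65-minute night (117 windows) for
breathing-rate recovery; 20 injected events for detector recall/precision
and 200 for the subtype classifier. A full 8-hour night runs end to end in
well under a minute on one core.
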