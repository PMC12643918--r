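---
title: "Delineating ABP and PPG waveforms with the iterative envelope mean"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Delineating ABP and PPG waveforms with the iterative envelope mean}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pulsefeat)
```

## The problem

A cardiac cycle of an arterial blood pressure (ABP) or photoplethysmography
(PPG) waveform carries five temporal landmarks: the systolic phase onset
(SPO, the foot of the upstroke), the systolic phase peak (SPP), the dicrotic
notch (DN, the local minimum marking aortic-valve closure), the diastolic
phase peak (DPP, the reflected/dicrotic wave), and the diastolic phase
endpoint (DPE, which coincides with the next cycle's SPO). Locating these
points per beat is the prerequisite for morphological pulse-wave analysis:
amplitudes, phase durations, areas, widths and derivative-based descriptors
all hinge on them. The difficulty is that the notch and the diastolic peak
ride on a large decaying trend and on reflection oscillations, and in many
cycles (especially PPG) they are barely visible in the raw trace.

`pulsefeat` implements a complete delineation-and-featurization pipeline:

1. cut the record into non-overlapping 4-second windows,
2. screen each window for artifacts,
3. low-pass filter (4th-order Butterworth, 16 Hz, zero-phase) and min-max
   normalize,
4. decompose the normalized window into a non-stationary component (NSTS)
   and a stationary trend (STS) by the iterative envelope mean (IEM),
5. delineate cardiac cycles on the NSTS under sign and separation
   conditions,
6. extract 852 named per-cycle features.

A synthetic pulse-train generator with analytic ground truth makes every
stage testable without clinical recordings, and an evaluation module scores
detections with the field's tolerance rule (a detection within ±8 ms of a
reference mark — 2 samples at 256 Hz — is a true positive) and
sensitivity / positive predictive value / F1 / error-rate metrics plus
Bland–Altman agreement.

## The iterative envelope mean

The IEM splits a signal into oscillation and trend by repeatedly removing
the midline between its envelopes. One iteration:

1. smooth the current residual with a Savitzky–Golay filter
   (window 25 samples at 256 Hz, polynomial order 3);
2. take the smoothed copy's local maxima and minima as knot *locations*,
   snapping each to the residual's own extremum within half a smoothing
   window (the smoothed copy robustly localizes turning points; the
   envelope should still pass through true signal values);
3. interpolate the residual's values at those knots with a shape-preserving
   monotone cubic — upper envelope through maxima, lower through minima —
   mirroring the outermost knots to the window edges, on a reflection-padded
   copy of the window so boundary cycles are not distorted;
4. subtract the sample-by-sample mean of the two envelopes.

Iteration stops when the maximum absolute envelope mean drops below
`beta` × the input's range (default `beta = 0.1`), or after `max_iter`
iterations. The final residual is the NSTS; the STS is defined as
input − NSTS, so the two components reconstruct the input exactly (to
floating-point zero) by construction. Runtime is linear in signal length at
fixed iteration count.

Numerical choices worth knowing:

* **Monotone cubic envelopes** (`stats::splinefun(method = "monoH.FC")`)
  avoid spline overshoot, which would create spurious NSTS zero-crossings
  near sharp landmarks.
* **Reflection padding** of about a quarter window on each side keeps
  envelope knots defined beyond the window edges; without it the first and
  last cardiac cycle of every window are visibly distorted.
* **Degenerate inputs** (monotone ramps, constants) have no usable extrema;
  the envelope then falls back to the chord through the first and last
  sample and the result is flagged.

## Landmark conditions on the NSTS

On the NSTS, systolic and diastolic peaks must have positive values and the
onset, notch and endpoint valleys negative values; the notch valley must lie
at least 0.1 s after the systolic peak, and the diastolic peak at least
0.1 s before the endpoint (`floor(0.1 * fs)` samples — exactly 25 at
256 Hz). Within those constraints the scan is:

1. **Systolic peaks anchor cycles.** A positive NSTS peak is a candidate
   when it reaches 60% of the upper-quartile positive-peak amplitude *and*
   its waveform value exceeds the window's 75th amplitude percentile (the
   same quantity the artifact screen uses: systolic peaks top the pulse,
   diastolic peaks do not). Candidates closer than the minimum cycle length
   (0.27 s, ~220 bpm) are pruned, keeping the taller.
2. **SPO** is the nearest negative valley before each systolic peak;
   **DPE** is the next cycle's SPO. The final cycle's endpoint falls back to
   the deepest negative valley one estimated period (median inter-SPP
   interval) after its onset. Cycle lengths must stay within 0.27–2.0 s and
   within 0.6–1.6 × the estimated period.
3. **DN** is the first negative valley ≥ 0.1 s after the SPP; **DPP** is the
   first positive peak after the DN, at least 0.1 s before the DPE and within
   0.35 period of the DN (later positive wiggles are pre-onset rebounds, not
   diastolic peaks). A cycle without a qualifying DN is dropped; a missing
   DPP is tolerated and reported as `NA`.
4. Cycles whose endpoint lies within 0.185 s of the window edge are dropped:
   without the next upstroke in-window, the NSTS there is not trustworthy.

**Position refinement.** The package deliberately does *not* report raw NSTS
extremum indices. The envelope midline has nonzero local slope wherever the
upper envelope descends from the systolic toward the diastolic knot, which
displaces shallow NSTS extrema by several samples relative to the waveform's
own turning points — more than the ±2-sample agreement the method is held
to, and not what an annotator marking the displayed waveform would produce.
The NSTS therefore decides *which* oscillations are landmarks (its strength
is exposing weak notches), and each position is refined to the corresponding
strict local extremum of the filtered, normalized waveform within less than
half the separation distance, so the refinement can never reorder landmarks.
Cycle onsets get one extra pass: all onset positions in a window are aligned
against the window's ensemble-average onset shape. On the flat diastolic
foot, additive noise scatters spurious local minima; averaging across beats
suppresses that noise roughly by the square root of the number of beats
while the steep upstroke pins the alignment. A boundary is only moved when
the per-beat minimum and the ensemble position disagree beyond lag
quantization.

## Preprocessing parameters

| parameter | default | meaning |
|---|---|---|
| `window_seconds` | 4 s | analysis window; no overlap |
| `butter_cutoff_hz` | 16 Hz | low-pass cutoff (zero-phase application) |
| `butter_order` | 4 | Butterworth order |
| `screen_min_peaks`, `screen_max_peaks` | 3, 10 | accepted pulse-peak count per window |
| `screen_percentile` | 75 | amplitude percentile a qualifying peak must exceed |
| `iem$sg_window` | 25 samples at 256 Hz | Savitzky–Golay window, scaled as `round(25 fs/256)` forced odd |
| `iem$beta` | 0.1 | stopping accuracy |
| `landmarks$min_separation_s` | 0.1 s | SPP–DN and DPP–DPE separation floor |

Screening counts strict local maxima on a lightly Savitzky–Golay-smoothed
copy of the window against the raw 75th percentile: the criterion targets
pulse peaks, and counting raw strict maxima would reject any noisy window
as "too many peaks". Screening precedes filtering; windows are filtered and
normalized individually after acceptance. Zero-phase filtering is used in
both recorded and streaming-replay modes so landmark times are not biased;
the filter is applied to a de-meaned, reflection-padded copy to suppress
start-up transients.

## The 852-feature manifest

Feature names follow the `<kind>_<FAMILY>_<...>` pattern with the signal
kind (`ABP`/`PPG`) as prefix; the 25 exemplar amplitude and duration
features keep their field-standard names (`ABP_AM_SPP_wrtSPO`,
`ABP_D_DN_wrtDPE`, …) and lead the manifest. Per-family sizes are fixed:
amplitude 30, amplitude ratio 210, duration 10, duration ratio 46,
average 40, median 20, RMS 20, skewness 1, kurtosis 1, area 40,
area ratio 180, width 36, frequency domain 12, first derivative 28,
second derivative 178 — 852 in total.

Generation rules, in brief: the 15 exemplar amplitudes (signed differences
of normalized values at landmark pairs, "wrtZero" measured on the
normalized window) are duplicated on the raw scale to reach 30; amplitude
ratios are all 210 ordered pairs of the 15 normalized amplitudes; the 10
durations are the exemplar time differences and the 46 duration ratios are
their 45 unordered pairs plus the systolic/diastolic phase-duration ratio
(SPO→DN over DN→DPE); averages, medians and RMS are taken over the 10
landmark-delimited segments of the normalized signal and its first
derivative (averages additionally on the raw signal and second derivative);
areas are trapezoidal integrals over the same segments for the normalized
signal, raw signal, |first| and |second| derivative, with area ratios the
ordered pairs of the normalized and raw segment areas; widths are measured
at 10–90% height in 10% steps on the systolic rise (9), at 10–95% in 5%
steps on the decay (18) and at 10–90% in 10% steps for the full pulse (9);
the 12 frequency-domain features are the fundamental, three harmonic
magnitudes and their ratios, spectral centroid, bandwidth, 85% rolloff,
flatness and total power of the mean-removed cycle; first- and
second-derivative families build on central-difference derivatives, the
second smoothed with the Savitzky–Golay window before the a–e wave extrema
are picked. The full membership is dumped by `write_manifest_md()` (or the
CLI `manifest` subcommand) for audit. Only the counts and the 25 exemplar
names are externally fixed; the remaining memberships are this package's
documented choices.

Incomputable entries (absent DPP, degenerate segments, missing
second-derivative waves, zero denominators) are `NA` sentinels — serialized
as empty CSV cells, never as zeros. For ABP cycles the per-cycle vitals are
SBP = raw maximum, DBP = raw minimum, and MAP = the arithmetic mean of the
raw samples: the full waveform is available, so the true mean is preferred
over the DBP + PP/3 approximation (configurable by computing it downstream
if desired).

## The synthetic generator

`synth_pulse_train()` emulates a radial-artery pressure recording: each
cycle is a phase-parameterized template of a systolic wave with a sharp
upstroke foot (a bi-Gaussian gated by a smoothstep at phase 0), a narrow
negative Gaussian "incisura" dip whose amplitude is `notch_depth` × 0.2 of
the pulse height (the dicrotic notch), and a dicrotic wave whose
exponential run-off decays across the cycle boundary, giving the next
onset a genuine diastolic left flank. Key properties, chosen once:

* every landmark is locally symmetric in the template, so the zero-phase
  16 Hz filter moves clean landmark extrema by at most ~2 samples (a
  property test checks this);
* `notch_depth = 0` broadens the dicrotic wave into a smeared shoulder and
  slope-matches it against the systolic decay so *no* local minimum
  survives — the DN-less morphology, flagged per cycle as
  `dn_visible = FALSE`;
* per-cycle periods carry log-normal jitter (CV 2% by default) to avoid
  exact-periodicity degeneracies;
* ground truth is computed on the noise- and drift-free composite signal;
  a cycle is *complete* (and enters the truth) only when its endpoint
  minimum lies at least 0.2 s inside the record, i.e. the next upstroke has
  begun. A 10-s record at 60 bpm therefore contains 8 complete cycles of
  its 10 nominal ones.

What the generator does **not** emulate: measured-beat morphology variety,
pathological waveforms, motion artifacts, colored noise, or sensor-specific
PPG nonlinearities. Passing the synthetic suites therefore demonstrates
that the algorithm chain is implemented correctly and is robust to additive
white noise and baseline drift at the stated levels — not that it attains
the same figures on clinical recordings.

## Evaluation conventions

Matching is greedy nearest-neighbour and one-to-one per landmark type;
tolerance defaults to ±8 ms. DPE is excluded from scored landmark types by
default since it coincides with the next SPO. The error rate uses the
printed asymmetric denominator ER = (FP+FN)/(TP+FP) verbatim;
`symmetric_er = TRUE` exposes the (TP+FP+FN) alternative for diagnostics.
Counts are pooled over cycles (not macro-averaged over windows). When
scoring a windowed detector on a continuous record, `cycles_in_windows()`
restricts both reference and detections to cycles wholly contained in
single analysis windows — a cycle straddling a window cut is invisible to
a windowed detector by construction, mirroring the per-window annotation
protocol.

## Problem sizes used by the test suite

The acceptance-style tests run the full pipeline on 200 independent 4-s
windows at 256 Hz with heart rates drawn uniformly from 50–110 bpm, clean
and with additive white noise at 2% of the systolic amplitude; the
streaming/recorded equivalence and Bland–Altman demonstrations use 60-s
records. IEM conservation is checked on 100 random signals. These sizes
keep the default suite in the low minutes on one CPU while exercising a
few hundred cycles per condition.

## Known limitations

* **Trend recovery is bounded by waveform asymmetry.** The NSTS converges
  toward a symmetrized oscillation, so the STS necessarily absorbs the
  asymmetric part of each beat: for realistic spiky pulse trains the STS
  carries cycle-rate ripple of roughly 0.06–0.15 of the pulse height
  (depending on morphology), while for near-symmetric oscillations a
  superposed slow drift is recovered to RMSE ≈ 0.002. The decomposition is
  a landmark-exposure device, not a general detrender, and should not be
  read as one for asymmetric signals.
* The fixed Savitzky–Golay window and stopping accuracy are not adapted to
  the data; heavy high-frequency artifacts call for dedicated denoising
  upstream of this pipeline.
* Landmarks are reported at integer sample indices; no sub-sample
  interpolation is attempted.
* The first partial cycle of a window and cycles ending within ~0.2 s of a
  window edge are not delineated; on continuous records the streaming and
  recorded modes are identical per complete window, and both inherit this
  edge behaviour.
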