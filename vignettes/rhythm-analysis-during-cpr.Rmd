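---
title: "Rhythm analysis during CPR: model, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Rhythm analysis during CPR: model, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cprsaa)
```

## The problem

Chest compressions corrupt the ECG with a large, quasiperiodic artifact that
spectrally overlaps every cardiac-arrest rhythm. A defibrillator's shock
advice algorithm (SAA) therefore cannot analyze the rhythm while CPR is
ongoing, and compressions must be paused for each analysis — pauses that
reduce the probability of defibrillation success. The specific failure mode
that has kept filtering approaches out of devices is **specificity**:
filtering residuals of nonshockable rhythms, above all asystole, look like
disorganized activity and draw false shock advices.

`cprsaa` implements a chain designed around that failure mode: suppress the
artifact with an adaptive filter that exploits compression timing, then
diagnose the *filtered* signal with a classifier trained for exactly that
kind of input, with a dedicated low-electrical-activity (LEA) gate in front
of it.

## Signal model and preprocessing

All analysis runs at 250 Hz (`resample_to_fs()`, polyphase rational
resampling) on an ECG band-limited to 0.5–30 Hz by a causal order-10
Butterworth band-pass — the monitor bandwidth of automated external
defibrillators. Two implementation choices matter:

* **Cascaded second-order sections** (`butter_sos()`): at 250 Hz the 0.5 Hz
  edge sits at 0.004 of Nyquist, where a direct-form order-10 polynomial
  loses precision; biquads keep every section well conditioned. The design
  is validated in the test suite against an independent Butterworth
  implementation.
* **DC-matched initial conditions** (`sos_apply(match_dc = TRUE)`): each
  section's state starts at its steady-state response to a constant equal to
  the first sample. A causal 0.5 Hz high-pass edge otherwise rings for
  several seconds after the record start; with matched states the response
  to a constant input is numerically zero from sample 0. Filtering stays
  strictly causal — a device cannot look ahead — so zero-phase filtering is
  deliberately not offered.

Records are cut into non-overlapping 9-s segments of three 3-s windows
(750 samples), aligned to the record start, trailing remainder dropped. A
3-s window suffices to characterize rate and morphology; the 9-s majority
vote suppresses spurious advice at rhythm transitions.

## The compression-artifact canceller

The artifact is modeled as five harmonics of the instantaneous compression
frequency with slowly varying amplitudes and phases. The frequency
$f_0(n) = 1/(t_k - t_{k-1})$ is piecewise constant between the compression
marks $t_k$; `lms_suppress()` accumulates the phase sample by sample
($\phi(n) = \phi(n-1) + 2\pi f_0(n) T_s$) so that rate changes never produce
phase jumps, and tracks, per harmonic, an in-phase and a quadrature
coefficient by a standard LMS update. That parameterization is algebraically
equivalent to the amplitude/phase form but linear in the coefficients, which
is what makes the LMS update valid and numerically robust. The filtered
signal is `s_filt = ecg - s_cpr`, exactly, at every sample.

Outside compression episodes (before the first mark, and more than one
period after the last) the artifact estimate is zero, coefficients frozen —
the record passes through untouched. Coefficients start at zero at each
episode start. Divergence (non-finite coefficients) raises an error naming
the step size.

**Step size.** The adaptation constant trades convergence speed against
distortion of the underlying rhythm: too large and the filter "tracks" the
VF itself into the artifact estimate, too small and it cannot follow
amplitude drift. The default `step_size = 0.003` comes from a calibration
sweep on synthetic mixtures: on a stationary artifact the steady-state
residual is 0.35 % RMS after 6 s, and on coarse VF corrupted at −5 dB the
in-band SNR gain averaged 12.5 dB (minimum 11.3 dB over eight seeds);
0.002–0.005 perform nearly identically, 0.01 and beyond degrade the SNR
gain. The value is exposed in `filter_config()` rather than hard-coded,
since its optimum depends on the artifact's non-stationarity.

## The six window features

Computed on each 3-s window of `s_filt` (`window_features()`):

| feature | definition | role |
| --- | --- | --- |
| `P_LEA` | energy of the 2.5 Hz high-passed window (order-5 Butterworth) | low in LEA rhythms |
| `L_min` | minimum curve length $\sum\sqrt{\Delta s^2 + T_s^2}$ over six 0.5-s subintervals | minimum electrical activity; floor 0.5 for a flat subinterval |
| `bS` | 10th percentile of the max-normalized squared-slope envelope | slope "baseline": low for organized rhythms, high for VF |
| `nP` | peaks of that envelope above a fixed threshold | deflection count |
| `P_fib` | power fraction in 2.5–7.5 Hz | where human VF concentrates power |
| `P_h` | power fraction in 12–30 Hz | heart-rate harmonics of organized rhythms |

The slope envelope is the 100-ms moving average of the squared first
difference; spectral features use a Hamming window and a zero-padded
1024-point FFT with the PSD normalized to unit total power over all
positive-frequency bins up to Nyquist (the plainest reading of "total
power").

Numerical conventions that were genuinely open and are fixed here:

* the envelope's moving average is **reflect-padded** at the window start so
  the first 100 ms are not biased low, and the normalization maximum is
  taken after padding;
* the percentile uses linear interpolation between order statistics
  (`quantile type 7`);
* `nP` counts **strict local maxima** above a threshold of 0.2 with a
  minimum separation of one slope window (100 ms), so ripple on a single
  deflection is never double-counted; peak heights are compared at 12
  significant digits so the count cannot depend on last-bit rounding of the
  envelope; the global maximum (height 1) always counts, hence `nP >= 1`
  for any non-degenerate window;
* an identically zero window is flagged degenerate with all features 0;
* `P_h`'s upper edge is the 30 Hz analysis bandwidth, configurable.

The amplitude unit is **millivolts** throughout. The LEA thresholds below
are unitful, and in mV the asystole definition (peak-to-peak < 0.1 mV)
lands far below them, which is what makes the gate effective; the unit is
nevertheless configurable by recalibrating the thresholds.

## The two-stage shock advice algorithm

A window is first screened by the LEA detector: `P_LEA < 0.44` **or**
`L_min < 0.63` (the published operating point; mV units) declares it
nonshockable without ever evaluating the SVM. This gate is the main
specificity device: asystole with filtering residuals rarely passes it.

Windows with electrical activity go to a Gaussian-kernel SVM on the four
standardized slope/spectral features,
$f(x) = \sum_i \alpha_i y_i e^{-\gamma\|x - x_i\|^2} + b$, shock iff
$f(x) > 0$ (the boundary is nonshockable — the conservative choice for a
device that interrupts CPR on a shock advice). Standardization uses
training-set means and **population** (divide-by-$n$) standard deviations;
that convention makes a two-point training column map exactly to
$\{-1, +1\}$ and is preserved in the serialized model. Each 9-s segment is
diagnosed Sh iff at least two of its three windows are Sh.

## Training

`train_saa()` mirrors the two stages:

1. **LEA calibration** (`calibrate_lea()`): exhaustive scan over candidate
   thresholds (the observed feature values plus midpoints — complete for
   threshold rules) on asystole vs. shockable windows, maximizing asystole
   detections subject to at most 5 % of shockable windows lost. Ties prefer
   fewer shockable losses, then smaller thresholds; the result is
   order-invariant. If no candidate pair satisfies the constraint the
   degenerate all-pass thresholds are returned with a warning flag.
2. **SVM grid search** (`svm_train()`): 5-fold cross-validation minimizing
   the balanced error rate $\mathrm{BER} = 1 - (\mathrm{TPR} +
   \mathrm{TNR})/2$ over $C \in 2^{-2..6}$, $\gamma \in 2^{-6..2}$ (grids
   bracketing the operating point $C = 8.5$, $\gamma = 0.1$ reported for
   clinical data; both configurable). Class weights default to inverse
   class frequency normalized to mean 1 — the weights themselves were not
   published. Folds are stratified by class and, when record identifiers
   are present, grouped by record so windows of one record never straddle
   folds (the clustering concern applied at training time); if a class is
   present in fewer than two records, grouping is impossible and folds fall
   back to window-level stratification. Ties break toward smaller $C$,
   then smaller $\gamma$; the model is refit on all data at the winner.

## What the synthetic generators emulate — and what they do not

The generators (`gen_rhythm()`, `gen_artifact()`, `gen_corpus()`) exist so
that every stage is testable without clinical data, and their defaults
encode the study conditions the method targets:

* **coarse VF**: narrow-band filtered Gaussian noise around a fibrillation
  frequency in 2.5–7.5 Hz with slow amplitude modulation, peak-to-peak
  above 0.2 mV (corpus draws: 0.4–1.5 mV, 3.5–6.5 Hz);
* **organized rhythms**: biphasic ~100-ms QRS-like deflections at 0.5–3.5 Hz
  over a small smooth baseline (corpus draws: 0.5–2 mV, 0.7–2.8 Hz);
* **asystole**: low-pass noise under the 0.1 mV definition cap (corpus
  draws: 0.02–0.08 mV);
* **artifact**: the exact five-harmonic forward model with jittered
  inter-compression intervals (3 % coefficient of variation by default —
  trained rescuers are metronome-regular), rates drawn from 88–156
  compressions/min (the published 5–95 % range, median 116), decaying
  harmonic amplitudes, and slow sinusoidal amplitude drift capped at 5 %/s;
  the compression-depth channel is a smoothed pulse train with peaks around
  36 mm (published median), so mark re-detection can be exercised;
* **mixtures**: artifact scaled to a target SNR measured as the power ratio
  inside 0.5–30 Hz — the band where the filter and features operate.

VF is *not* an electrophysiological model, organized rhythms have no P or T
waves and no rate variability, the artifact follows the harmonic model
*exactly* (no model mismatch), and marks are noise-free. Passing the
end-to-end test therefore shows that the chain recovers what its own model
family generates under realistic rates, amplitudes and SNRs — it does not
certify clinical performance, which the published study measured on
out-of-hospital cardiac-arrest data. In particular the synthetic corpus is
easier than clinical data (the end-to-end test reaches Se and Sp near 1.0,
versus 91.0 %/96.6 % reported on clinical segments), precisely because
residuals of the exact harmonic model are small.

## Problem sizes used in the shipped checks

The test suite trains and evaluates on a 72-record corpus (216 nine-second
segments, classes balanced, SNR 0 dB, fixed seed), splitting records
alternately into training and test halves. Filter physics is checked on
12-s stationary artifacts and 20-s VF mixtures at −5 dB over three seeds;
oracle equivalence of the six features uses 100 random windows. These sizes
keep the whole suite under a minute of filter computation while leaving
every claim at its stated tolerance.

## Evaluation and uncertainty

`evaluate_corpus()` reports sensitivity (shockable = positive class),
specificity, BER and a per-class breakdown at window and segment level.
Because consecutive windows of one record are strongly correlated,
confidence intervals come from a **record-level percentile bootstrap**
(`cluster_ci()`: resample whole records, one-sided lower bound, seeded) —
the same clustering concern the published analysis addressed with
generalized estimating equations, handled here without a parametric working
model, and labeled as "record bootstrap" in every report so the two are
never conflated. `ppv()` converts an operating point and a VF prevalence
into the confidence in a shock advice; `auc()` uses the Mann–Whitney
identity with midrank ties.

## Known limitations

* The LMS step size and the LEA thresholds are calibrated quantities; the
  shipped defaults are justified on synthetic data (step size) and the
  published operating point (thresholds), not on clinical recordings.
* Compression marks are taken as given (or detected from a clean synthetic
  depth channel); real mark detection from noisy assist-pad signals is out
  of scope.
* Only the compression-depth reference is supported — no impedance or
  acceleration channels, and no alternative filters (Wiener, RLS, Kalman,
  matching pursuit).
* No probability calibration on the SVM discriminant; decisions are hard
  Sh/NSh.
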