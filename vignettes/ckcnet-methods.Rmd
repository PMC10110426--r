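---
title: "Detecting movement-evoked cortical responses and their directed networks with ckcnet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting movement-evoked cortical responses and their directed networks with ckcnet}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", fig.width = 7)
library(ckcnet)
```

## The problem

Repetitive, machine-actuated limb movement (for example a pneumatic balloon
flexing an infant's fingers at a constant 1.78 Hz) drives a steady-state
proprioceptive response in the sensorimotor cortex. Because every movement
cycle delivers two afference volleys — one for flexion, one for extension —
the cortical response concentrates at the *first harmonic* of the movement
rate, 2 × 1.78 = 3.56 Hz. Detecting that response, and mapping the cortical
network it recruits, gives a controlled, fully automatable probe of
somatosensory function in subjects who cannot cooperate with conventional
testing.

`ckcnet` implements the complete analysis chain on multichannel scalp EEG:

1. **Preprocessing** — zero-phase band-pass filtering, resampling,
   trigger-locked epoching, amplitude-based artifact rejection.
2. **CSD transform** — a reference-free spherical-spline surface Laplacian.
3. **CKC detection** — Morlet-wavelet phase decomposition, inter-trial
   phase coherence (ITC), a channel-level corticokinematic coherence (CKC)
   metric, parametric Rayleigh significance, and FDR control.
4. **Directed connectivity** — narrowband Hilbert phases of cortical parcel
   signals and directed phase transfer entropy (dPTE).
5. **Group and individual network metrics** — Consistent Networks,
   the Spreading Index, laterality and symmetry.
6. **Synthetic data** — generators for every input, so the full pipeline is
   exercised and validated without any clinical recording.

## Detection model

Epochs run from 200 ms before to 900 ms after a stimulation trigger
(1,100 ms, two full movement cycles at the 561.8 ms inter-stimulus
interval). Consecutive epochs may not overlap; triggers are consumed
greedily in time order, which deterministically maximizes the epoch count —
with jitter-free triggers every second trigger starts an epoch, i.e. one
epoch per 1.124 s. Each epoch is detrended by its per-channel mean ("local
mean" subtraction).

The CSD transform interpolates the scalp potential with spherical splines
(flexibility `m = 3`, smoothing `lambda = 0`, 50 Legendre terms) and applies
the surface Laplacian, scaled by the squared head radius (default 0.092 m,
a neonatal-scale single sphere). The operator is linear and
reference-invariant: adding any common time series to all channels changes
nothing. With `lambda = 0` an ill-conditioned spline system is an error, not
a silent regularization.

Phases come from convolution with complex Morlet wavelets on 40
log-spaced bins over 0.5–12 Hz, with the bin nearest 3.56 Hz *pinned* to
exactly 3.56 Hz. A constant 7 cycles per kernel reproduces the intended
resolution at the response bin: measured full widths at half maximum of
roughly 740 ms (envelope) and 1.18 Hz (amplitude spectrum). These two
printed values are mutually inconsistent with an exact Gaussian
time–bandwidth product by about 1%, so the package checks both at ±2%.
Epochs are shorter than the kernels' full support; convolution is
zero-padded and cropped to the epoch window, and the first and last 200 ms
of each epoch are excluded from all metrics, which confines (but does not
eliminate) edge effects. This is inherent to the paradigm's short epochs,
not an implementation shortcut.

Per channel,

- CKC = mean ITC at the pinned bin over epoch time 0–700 ms,
- the aggregated P value is the mean over the same samples of the Rayleigh
  closed form `P = exp(sqrt(1 + 4N + 4N^2(1 - ITC^2)) - (1 + 2N))`,
- detection requires the aggregated P below `alpha = 0.01` *and* survival
  of Benjamini–Hochberg FDR across the 21 channels at `q = 0.01`.

Averaging P values over correlated time samples makes channel-level
inference *conservative*: under an end-to-end null (zero response
amplitude) the empirical channel rate at `alpha = 0.01` is far below 0.01.
The calibration of the Rayleigh machinery itself is exact: when each epoch
contributes a single phase (as a narrowband null does), the aggregate
equals one Rayleigh P and the empirical type-I error sits in the nominal
range. Both facts are asserted in the test suite.

An FFT-based alternative (`ckc_fft()`) takes per-epoch spectral phases at
the bin nearest 3.56 Hz (zero-padded to ≤ 0.25 Hz spacing). On synthetic
data the two estimators' peak CKC values correlate at r ≈ 0.99. One caution:
on the *stationary* synthetic response the FFT estimator reads slightly
higher than the wavelet CKC at every signal-to-noise ratio we measured, so
the often-reported SNR advantage of wavelet CKC — which stems from its
adaptation to nonstationary responses in real recordings — is not
reproduced by this generator and is not asserted anywhere.

## Directed connectivity model

Parcel signals (58 parcels, 29 per hemisphere, lobe-labelled F/C/T/O) are
accepted from any user-supplied linear projection of the channels;
source reconstruction itself is out of scope. Signals are constrained to
3.56 ± 0.3 Hz with order-626 Hamming FIR high- and low-pass filters applied
forward–backward, then reduced to analytic-signal phases; `fir_order`
samples are discarded at both ends. The forward–backward pass is computed
as a single FFT convolution with the filter's autocorrelation kernel,
verified in the tests to match time-domain `filtfilt` to 1e-10.

Phase transfer entropy uses binned phase histograms (natural logarithm):

    PTE_xy = H(y_t, y_{t-d}) + H(y_{t-d}, x_{t-d}) - H(y_{t-d}) - H(y_t, y_{t-d}, x_{t-d})

with the bin count from Scott's rule (`3.49 · SD · n^(-1/3)` on the pooled
phases) and the prediction delay `d` from the sign-change heuristic
(samples × series / total phase sign changes, ≥ 1). The two directions are
normalized to `dPTE_xy = PTE_xy / (PTE_xy + PTE_yx)`, so dPTE is
scale-invariant, pairs sum to exactly 1, and 0.5 means no preferred
direction. Estimator noise can make one raw PTE marginally negative; the
pair is clamped so dPTE stays within [0, 1] without breaking antisymmetry.
A binary fidelity mask (symmetric, diagonal invalid) removes unreliable
parcel pairs from every count and mean; degenerate edges (zero total PTE)
are recorded as missing, never raised as errors. Phases are taken from the
continuous parcel series, not epoch-concatenated — the choice matters
little at these durations and is the simpler contract.

### Group and individual metrics

The **Consistent Network** keeps each subject's top `k = 5%` of valid
directed edges (ties broken by raw PTE, then labels — fully deterministic),
counts appearances across subjects, and tests each edge against a
right-tailed exact binomial null (success probability `k`) with BH-FDR over
the valid edges at `alpha = 0.05`. With 20 subjects and `k = 0.05`, four
appearances are needed before FDR (`P(X ≥ 3) = 0.075`, `P(X ≥ 4) = 0.016`).

The **Spreading Index** z-scores every stimulation-condition edge against
the pooled mean and SD of the subject's own control-condition dPTE values
(typically centred on 0.5), selects within a hemisphere the 4 parcels with
the most significant outbound edges (right-tailed, `P < 0.01`; ties by
summed outbound z, then labels), and reports the percentage of significant
outbound edges among all mask-valid outbound edges of those sources. Masked
edges are "not possible" and never enter the denominator. Without a control
recording the SI is undefined and reported as skipped. **Laterality** is
100·contra/(contra+ipsi) and **symmetry** 100·min/max across stimulation
sides; for channel-level CKC the hemisphere value is the maximum over that
hemisphere's channels (midline excluded) by default, with the mean
available — the choice of summary is genuinely open and exposed.

## The synthetic-data generators

The generators define the study conditions used throughout the tests:

- **Triggers**: 1.78 Hz with Gaussian jitter applied to the inter-stimulus
  intervals (SD 2.9 ms), reproducing the stimulator's reported ISI
  statistics directly.
- **Scalp recordings**: 21-channel 10–20 montage at 250 Hz; 1/f amplitude
  background with a shared common-mode term (mixing 0.3) so the CSD has
  spatial structure to remove; default background 20 µV RMS. The response
  is a 3.56 Hz sinusoid re-phased at every trigger with a wrapped-Gaussian
  per-trigger phase offset — the steady-state component is the analysis
  target, so no transient evoked shape is modelled. The default response
  amplitude makes the response RMS equal the realized background RMS inside
  3.56 ± 0.5 Hz (in-band SNR 1); the level is a calibrated choice, since no
  real-data SNR is available to copy.
- **Artifacts**: EMG (band-limited white noise, 5–70 Hz), device/mains
  (50 Hz plus harmonics on a broadband floor, 2–125 Hz), respiration
  (~0.8 Hz bump train, band-limited 1–30 Hz) and ECG-like biphasic spikes
  (~2.4 Hz, 2–35 Hz), all unit-RMS per channel.
- **Parcel signals**: stochastic phase oscillators at the carrier with
  per-sample phase-noise SD 0.05 rad. A coupling edge makes the target's
  phase relax towards the source's phase `lag` samples earlier
  (lag-compensated sine coupling). An earlier design — adding a lagged,
  scaled copy of the source signal — turned out to carry almost no
  *recoverable* phase-transfer information: with a static linear mixture
  the target phase is an instantaneous function of two smooth narrowband
  processes, and measured direction recovery stayed near chance at any
  duration or bandwidth. The phase-coupled oscillator keeps the ground
  truth (information flows source → target with a known lag) and is
  recovered by dPTE in essentially every seed.

What the generators deliberately do **not** model: biophysically realistic
neonatal EEG (sleep architecture, trace alternant), volume conduction from
cortical sources to electrodes, and nonstationary response morphology.
Passing tests therefore demonstrate the *estimators'* correctness and the
pipeline's calibration under known ground truth — not clinical performance
on real recordings.

## Numerical choices

- Resampling is spectral (FFT truncation) after the anti-alias band-pass;
  for a signal already limited to 30 Hz this is exact at any rational rate
  ratio. Trigger times stay in seconds and are never converted through
  sample indices, avoiding rounding drift.
- Wavelet kernels are truncated at ±4 temporal SDs and unit-energy
  normalized; zero-magnitude coefficients yield `NA` phases rather than
  arbitrary angles.
- Rayleigh P values are clipped at 1e-300; entropies use the natural log
  (dPTE cancels the base); large sparse joint histograms are counted by
  radix sort rather than dense tabulation.
- All generators draw from an isolated RNG stream (the caller's `.Random.seed`
  is saved and restored), so identical seeds give bit-identical outputs
  regardless of context.

## Problem sizes used in validation

The validation suite and the acceptance script use scaled-down but
statistically meaningful sizes chosen as a deliberate design point:
20-recording synthetic cohorts of ≥120 s (≈106 epochs) for detection rates,
30 recordings spanning phase jitter 0–π for method agreement, 50
two-channel 60 s pairs for the dPTE null, 10^6 draws for the Rayleigh
Monte-Carlo, and 20-seed recovery runs for SI and coupling direction.
The one boundary worth knowing: at in-band SNR 1 and phase jitter 1.0 rad
the per-recording detection probability at 100 epochs is ≈0.97, so a
20-recording cohort occasionally reports 95% rather than 100% — the misses
are single-strong-channel recordings whose aggregated P (~1e-3) fails the
BH rank-1 threshold of 0.01/21.

## Known limitations

- The spherical-spline CSD uses one idealized sphere and a fixed montage;
  no per-subject electrode digitization.
- PTE bin counts and delays follow the cited histogram formulation; other
  estimators (binless, symbolic) may behave differently near the
  no-coupling floor.
- The FFT/wavelet SNR comparison direction on real, nonstationary data is
  not reproducible from this generator (see above).
- Network metrics are reported per subject; cohort statistics (group
  comparisons, clinical correlations) are left to the user's own analysis.
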