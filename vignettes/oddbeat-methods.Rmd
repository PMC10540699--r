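---
title: "Simulating and analysing rhythmic auditory oddball EEG with oddbeat"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating and analysing rhythmic auditory oddball EEG with oddbeat}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The experiment oddbeat emulates

`oddbeat` implements, end to end, an auditory experiment that crosses
predictions about stimulus *content* ("what": which tone frequency comes
next) with predictions about stimulus *timing* ("when": when the next tone
arrives), at two temporal scales. Listeners hear trials of seven ascending or
descending musical scales, eight tones per scale (56 tones per trial), each
tone 166 ms long, with every second tone 10 dB quieter so that tones group
into duples. Three timing regimes are blocked:

* **isochronous** — every onset asynchrony is 247 ms: timing is predictable
  at both the element rate (1/0.247 s ≈ 4.048 Hz) and the pair rate
  (1/0.494 s ≈ 2.024 Hz);
* **interval-based** — the within-pair interval is fixed at 247 ms but pair
  onsets are jittered (±16.6% or ±33.3% of 247 ms relative to the expected
  494 ms grid, anchored to the actual previous pair onset);
* **beat-based** — pair onsets sit on a fixed 494 ms grid but the within-pair
  interval is jittered by the same four multipliers.

Content predictions are violated by two deviant types per trial: an
*interval-defining* (ID) deviant replacing a scale-final (pair-final) tone,
and a *beat-defining* (BD) deviant replacing a scale-penultimate
(pair-initial) tone, each with a frequency 20% outside the scale's range.
Position-matched *designated standards* in unaltered scales serve as their
ERP controls, and the onset asynchrony immediately before every deviant or
designated standard is reset to exactly 247 ms so that baselines are
comparable across timing regimes. Half of the trials additionally contain an
immediate tone repetition — the target of the behavioural decoy task.

The scientific questions this design supports are (1) whether EEG tracks the
element and pair rates with condition-specific phase consistency (inter-trial
phase coherence, ITPC), (2) whether mismatch responses (MMRs) to deviants are
modulated by timing predictability in a *congruent* way — ID deviants
enhanced under interval-based timing, BD deviants under beat-based timing —
and (3) whether these neural indices relate to behavioural benefit.

## The generative model of the synthetic EEG

Because desk-scale work cannot assume access to recordings, the package's
`synth_recording()` produces 64-channel EEG whose statistical structure is
exactly what the analysis assumes:

* **1/f background noise**, spectrally shaped white noise with exponent 1.0
  and per-channel RMS `noise_scale` (default 5 µV);
* **tone-evoked kernels** (an N1-P2-like biphasic waveform, fronto-central
  topography) at every tone onset, scaled by the tone's level so quiet tones
  evoke smaller responses;
* **mismatch kernels** on every deviant: a negative component peaking at
  198 ms (inside the 173–223 ms analysis window) with an anterior-negative /
  posterior-positive topography, as expected for an MMN under average
  reference;
* **congruence kernels** only on temporally congruent deviants (ID ×
  interval-based, BD × beat-based): a negative component peaking at 155 ms
  (inside 130–180 ms) over left central-posterior channels;
* **entrainment**: per-trial sinusoids at exactly 4.048 and 2.024 Hz whose
  trial-wise phase offsets are von Mises with concentration κ. Injecting
  coherence through κ rather than through evoked periodicity gives direct,
  analytic control of the resulting ITPC. κ is gated by rate × condition ×
  experiment half; at the pair rate in the beat-based condition it rises from
  the first to the second half, reproducing the learning-like split-half
  pattern;
* **blink artifacts**: 400 ms biphasic templates with Poisson arrivals,
  maximal at Fpz and decaying with scalp distance.

`synth_cohort()` adds a multiplicative log-normal subject random effect
(SD 0.2) to all effect amplitudes and gives every subject an independent
schedule, recording, and response table derived from one master seed.

What the generator deliberately does *not* emulate: biophysical forward
models (no lead fields), correlated sensor noise, non-stationary artifacts
other than blinks, and the spectral fine structure of real auditory cortex
responses. Passing recovery tests on these simulations therefore demonstrates
that the *analysis chain* is correct and calibrated — not that the effects
exist in any particular real dataset.

## Analysis chain

**Preprocessing.** High-pass 0.1 Hz, band-stop 48–52 Hz, resampling to
300 Hz, low-pass 90 Hz, all zero-phase Butterworth of order 5. The filters
are realized in the frequency domain by applying the squared analog magnitude
response — precisely the gain of a forward–backward pass — because the
transfer-function recursion is numerically unstable at a normalized cutoff of
0.1 Hz / 1024 Hz. Resampling is Fourier resampling (ideal zero-phase).
Blinks are detected on Fpz (1–10 Hz band, peaks above median + 3 scaled MAD,
500 ms refractory — these detection constants are package choices, not taken
from any reference), blink-locked averages are formed over −200…600 ms, and
the top two spatiotemporal principal components of that average are projected
out of all channels. Signals are then re-referenced to the channel average.

**Epoching.** Deviants and designated standards are cut from −50 to +247 ms
(inclusive endpoint: 90 samples at 300 Hz) and baselined on −25…+25 ms, a
window symmetric about the onset that avoids contamination from the dense
tone train. Scales containing a repetition are excluded. Epochs pass through
denoising source separation (DSS): whitening by the ridge-regularized total
covariance (ridge 1e-9 × mean eigenvalue), PCA of the trial-average
covariance in the whitened space, retention of the top 8 components
(default), and back-projection. Condition ERPs use robust averaging —
bisquare weights (tuning 4.685) on residuals standardized by the per-channel
scaled MAD, at most 10 iterations, tolerance 1e-6 — followed by a 48 Hz
zero-phase low-pass.

**ITPC.** Whole-sequence epochs (onset to offset of each trial, no padding)
are reduced to phases by an exact-frequency DFT at 4.048 and 2.024 Hz and
their neighbor frequencies (3.974/4.124 and 1.949/2.099 Hz) — an explicit
complex-exponential inner product rather than an FFT bin grid, because trial
durations differ across conditions. Coherence uses the unnormalized form
([Σcos φ]² + [Σsin φ]²)/N, which equals 1 in expectation under uniform
phases and N at perfect coherence; a `normalized = TRUE` variant returns the
conventional resultant length in [0, 1] (a monotone transform at fixed N, so
condition contrasts are unaffected). Peak tests are paired t-tests of
channel-averaged target-frequency ITPC against the mean of its neighbors;
condition effects are per-channel one-way repeated-measures ANOVAs on
smoothed topographies with cluster-level permutation correction; split-half
tests repeat the channel-averaged ANOVA per experiment half with
Benjamini-Hochberg correction over the four rate × half tests.

**ERP statistics.** Subject cell maps are smoothed spatially with a Gaussian
kernel of FWHM 5 on the projected montage scale (the montage grid is built so
nearest neighbors are 5 units apart, making the kernel the scalp-map analog
of a mild image smoothing). The omnibus test is a 3 × 3 within-subject ANOVA
(Contents × Time) per channel-time point; the planned congruence test is the
2 × 2 interaction with weights (+1, −1, −1, +1) on (ID × interval,
ID × beat, BD × interval, BD × beat), which is exactly zero under additive
cell means. Familywise control over channels × time uses permutation
max-cluster-mass inference: cluster-forming threshold p < 0.001, spatial
adjacency = projected distance ≤ 1.5 × the median nearest-neighbor distance,
temporal contiguity along the epoch, and a null distribution from subject
sign flips (contrasts) or within-subject label permutations (ANOVAs). A
permutation scheme was chosen over random-field theory because it gives
exact FWE control without assuming a smooth Gaussian field on an
interpolation grid. The standards-only control applies the identical 2 × 2
machinery to the designated standards split by position type.

**Behaviour and brain-behaviour.** Hits are responses within (0, 2] s of a
repetition (the exclusion bound doubles as the scoring window); mean RTs from
correct trials are log-transformed. Accuracy and log RT enter one-way
within-subject ANOVAs over Time with FDR-corrected paired post-hocs;
half-wise changes use exact Wilcoxon signed-rank tests (zeros dropped,
p = 1 when no nonzero differences remain). The brain-behaviour stage
regresses the accuracy difference (interval-based − beat-based) on three
neural indices — the second-half pair-rate ITPC difference, the congruence
index, and the mismatch index — excludes subjects with Cook's distance above
5 × the mean, and reports Bonferroni-corrected Pearson correlations among
all measure pairs.

## Parameters that matter, and how the defaults were set

| parameter | default | units | role |
|---|---|---|---|
| `noise_scale` | 5 | µV RMS | 1/f background level |
| `erp_amp` | 0.8 | µV | tone-evoked kernel peak |
| `mismatch_amp` | 5 | µV | deviant MMR kernel peak |
| `congruence_amp` | 8 | µV | congruent-deviant kernel peak |
| `entrain_amp` element / pair | 5 / 0.5–3 | µV | oscillation amplitude per condition |
| `entrain_kappa` | 0–30 | – | phase concentration per rate × condition × half |
| `blink_rate_hz`, `blink_amp` | 0.05, 120 | Hz, µV | artifact load |
| `subject_sigma` | 0.2 | log units | between-subject amplitude spread |

The source experiment reports its effects as test statistics, not in
generative units (µV of an interaction kernel), so the effect-size defaults
cannot be copied from anywhere. They were fixed once by a calibration run at
the package's simulation scales — the values above recover each targeted
effect comfortably above an 80% replicate rate at cohorts of 8 subjects and
6-block schedules, while zero-effect data keep the familywise error at its
nominal level. They are deliberately generous relative to typical
physiological amplitudes because the simulated designs are two orders of
magnitude smaller than a real session; they are effect sizes for a test bed,
not claims about cortex. The κ pattern encodes the
qualitative structure: element-rate locking strong under isochronous and
beat-based timing and weak under interval-based timing; pair-rate locking
present only under beat-based timing, and only in the second experiment half.

## Simulation scales

Full-scale synthesis (240 trials × ~13.7 s × 1024 Hz × 64 channels) produces
~2 GB per subject, which is out of proportion for testing a pipeline. The
test suite and examples therefore generate recordings directly at the 300 Hz
analysis rate (the generator's sampling rate is a parameter; the 1024 Hz
default emulates the acquisition hardware and is exercised by the
filter-chain tests, which feed 1024 Hz signals through the full chain) and
use shortened schedules: 3 blocks × 2 trials for null cluster calibration,
6 blocks × 4 trials for effect recovery, cohorts of 7–8 subjects, and
100-permutation cluster tests. The split-half machinery
divides each condition's trials into consecutive halves whatever their
number; the 40 + 40 split of the full design is the special case at full
scale. Index-level analyses (correlation recovery at n = 18) simulate the
four subject indices directly from their joint distribution rather than from
EEG, since only their covariance structure is at stake.

## Numerical choices and degenerate inputs

* Exact-frequency DFT agrees with a zero-padded FFT evaluated at the same
  frequency to better than 1e-6 relative error (tested).
* FFT work is padded to 5-smooth lengths; boundary handling is reflection
  padding, so filtering is zero-phase with no wrap-around artifacts.
* Robust averaging falls back to the running average wherever all trial
  weights vanish, and returns the plain mean for identical trials.
* DSS regularizes rank-deficient covariances with a documented ridge;
  `n_keep = n_channels` reproduces the input to machine precision.
* Cluster inference refuses fewer than 100 permutations; permutation p-values
  use the add-one convention (never exactly zero).
* Degenerate post-hoc differences (zero variance) yield t = 0, p = 1 when
  the mean difference is zero, and p = 0 with infinite t otherwise.
* The average reference is a projection (idempotent); applying it twice is
  a no-op, which is tested.

## Known limitations

* The congruence and mismatch topographies are single fixed dipolar patterns;
  real MMR topographies vary across subjects.
* Sensor noise is channel-independent 1/f; real EEG noise is spatially
  correlated, which makes the DSS and cluster tests here somewhat easier than
  in real data.
* The behavioural generator draws trials independently; sequential effects
  (post-error slowing, fatigue) are not modelled beyond the half-wise RT
  shift.
* Stimulus ITPC uses the Hilbert envelope of a 5-harmonic synthetic timbre,
  not a resynthesized instrument note; only envelope periodicity matters for
  the rates analysed.
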