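---
title: "Methods: fitting gait parameters from cerebral blood-oxygen signals"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: fitting gait parameters from cerebral blood-oxygen signals}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Rehabilitation exoskeletons need an estimate of the wearer's intended gait —
how fast they mean to walk and how long a stride they mean to take — and for
patients with poor or absent lower-limb EMG that estimate must come from
somewhere else. fNIRS measures cortical hemoglobin concentration changes
(HbO, HbR, and their sum HbT) over motor-related regions and is robust
enough to wear while walking. `nirgait` implements a complete pipeline that
regresses two continuous gait parameters — a walking-speed staircase and a
stride-length staircase, both read from a knee-mounted inertial sensor —
from multichannel hemoglobin time series, and adapts the fitted model to new
individuals with a retention gate.

Because no raw recordings ship with the package, a seeded synthetic cohort
generator with known ground truth stands in for the study data; every claim
the test suite makes is a claim about recovery of that known structure.

## Signal conditioning

**Hemoglobin side.** Each channel is baseline-shifted by subtracting its
first sample, then decomposed into five physiological bands with
second-order Chebyshev type-I band-pass filters (0.5 dB passband ripple):

| band | range (Hz) | physiological source |
|------|-----------|----------------------|
| 1 | 0.6–2.0    | cardiac pulsation |
| 2 | 0.145–0.6  | respiration |
| 3 | 0.052–0.145| myogenic activity |
| 4 | 0.021–0.052| neurogenic activity |
| 5 | 0.0095–0.021| endothelial (metabolic) activity |

All filters are applied forward–backward. The filter order is nominally 2;
zero-phase application doubles the effective order and squares the magnitude
response. Zero-phase filtering is essential here because feature windows and
staircase targets must stay time-aligned — a causal filter would shift the
hemodynamic features relative to the gait they are regressed on. Plain
forward–backward filtering leaves start-up transients at the trace ends, so
the series is padded by odd reflection (up to 100 samples per end) before
filtering and trimmed afterwards. The filters were checked to be
numerically stable at a 10 Hz sampling rate even for the 0.0095–0.021 Hz
band (maximum pole modulus ≈ 0.998).

**Gait side.** The knee angular-velocity and angle series pass through a
second-order Butterworth low-pass at 6 Hz (zero-phase), rectification, and
a centered moving average (default 0.25 s — deliberately shorter than the
shortest plausible gait cycle so the inter-cycle minima survive smoothing;
edges shrink the window rather than padding). Gait cycles are delimited at
local minima of the smoothed envelope, with minima closer than 0.4 s pruned
(the deeper minimum wins) to stop sensor noise from splitting cycles. The
first and last cycles, which the trace boundaries truncate, are flagged
partial and excluded from training targets.

**Staircase targets.** Within one gait cycle the fitted parameter is
treated as constant, so each sample is replaced by its cycle's maximum of
the processed series ("digital step" processing). The staircase value is
assigned over the half-open interval from one cycle start to the next,
which makes the output invariant to permutations of samples within a cycle
— a property the test suite asserts directly.

## Feature battery

Features are extracted over sliding windows (default 5 s, stride 0.5 s,
end-aligned so each row is time-stamped where its target is read). The 5 s
window is a compromise: long enough for stable statistics of the cardiac
and respiratory bands at 10 Hz, short enough to give ~100 rows per minute
of recording. Oscillations slower than the window (bands 3–5) contribute
through their local level and trend rather than through resolved cycles;
this is an inherent limit of windowed statistics, not of the filter bank.

Per window, band, species and channel, nine time-domain statistics are
computed: energy, mean, population standard deviation, peak (max absolute
value), range, kurtosis (fourth standardized moment), skewness, number of
zero crossings (strict sign changes, zeros inheriting the previous sign),
and Shannon entropy of a 16-equal-width-bin histogram over the window's own
range. Degenerate conventions are fixed: a constant window has sd 0 and
skewness, kurtosis and entropy defined as 0. Spatial structure enters as
the Pearson correlation of every unordered channel pair within the window,
in lexicographic order. For C channels this gives
`5 bands × 3 species × (9 C + C(C−1)/2)` columns — 1,035 for the default
six-channel montage — and the count formula is tested for general C.

## Hybrid feature selection and reduction

Selection combines a filter stage with an embedded stage:

1. **Screen**: p = |Pearson correlation| of each column with the staircase
   target; keep p strictly above 0.3. The absolute value is deliberate —
   HbR couples with opposite sign to HbO, and an anti-correlated feature is
   exactly as useful to a regressor.
2. **Embed**: gradient-boosted regression trees (100 rounds, depth 3,
   learning rate 0.1, single-threaded, seeded) fitted on the retained
   columns; each feature's total gain is its embedded coefficient c.
3. **Combine**: `f_score = 2 p |c| / (p + |c|)`, the harmonic mean, so a
   feature must score on *both* criteria; the guard at p + |c| = 0 returns
   0. Ties in the top-k cut (default k = 100) break toward the smaller
   feature id for determinism.

The retained top-k columns then pass through a single-hidden-layer
autoencoder (tanh encoder, linear decoder, default 20 latent units) trained
with full-batch Adam on standardized inputs to minimize mean-squared
reconstruction error, with patience-8 early stopping on the training loss.
Twenty latent units compress the ~100 selected columns about 5:1 while
keeping the reconstruction of low-rank synthetic fixtures nearly exact,
which the tests verify.

Both the selection and the autoencoder are fitted once on the
cross-validation subjects only and applied frozen to test and adaptation
subjects. Within the cross-validation loop the folds reuse that same
reduction rather than refitting it per fold; the honest generalization
boundary is the subject-level train/test split, and per-fold refits would
triple the runtime for a marginally more pessimistic fold metric. This is a
deliberate design choice, documented here because reasonable
implementations differ on it.

## Sequence regression

The regressor is an LSTM (one layer, 64 hidden units by default) reading
the last 10 window feature vectors and emitting the staircase value at the
final window, trained separately per gait parameter. Features and target
are Z-score normalized with statistics from the training rows only;
constant columns map to 0. Training uses minibatch Adam (batch 128,
learning rate 1e-3), an L2 penalty (1e-4) on the weight matrices, and a
"forgetting rate" of 0.2 interpreted as recurrent dropout: one Bernoulli
mask per sequence, shared across timesteps, applied to the hidden state
entering the gates with inverted scaling. (Two other readings of the term —
exponential decay of the recurrent state, or a replay ratio in the
adaptation stage — were considered and rejected as less standard; the
parameter is config-exposed so the interpretation is at least explicit.)

Cross-validation is subject-wise: subjects are partitioned into 4 folds, so
no individual contributes to both sides of a fold. Each fold trains up to
200 epochs and stops early when the validation RMSE has not decreased for 8
consecutive epochs, restoring the best checkpoint. The deployable model is
then refit on all cross-validation subjects for the median of the per-fold
best epoch counts — with no validation set left, the fold-calibrated epoch
budget stands in for early stopping.

Sequences never straddle trials: each row's history is drawn from its own
trial, padded at the trial start by repeating the first row.

## Individual adaptation with an R² gate

For a new individual, rows are split time-ordered: the first 70% are
adaptation rows, the last 30% the gating slice. The model continues
training briefly (20 epochs, learning rate 2e-4) on the adaptation rows;
R² on the gating slice is computed before and after, and the update is kept
only if R² strictly improved. The gating slice is disjoint from the
adaptation rows precisely so that the gate cannot be trivially
self-confirming. The reported post-adaptation R² therefore can never fall
below the pre-adaptation value — an invariant the tests assert over many
seeded subjects — and under genuine inter-individual gain differences the
average improvement is positive.

## Evaluation metrics

Two metrics, both computed on staircase rows (partial edge cycles
excluded):

- relative RMSE `= sqrt(mean(((pred − real)/real)^2)) × 100`, in percent.
  It is scale-invariant but not shift-invariant, and it divides by the true
  value pointwise, so the staircase's strict positivity matters; an
  epsilon guard (1e-9) turns a degenerate target into a loud error rather
  than a silent huge number.
- R² `= 1 − SS_res/SS_tot`, with SS_tot about the mean of the true series.

Both are checked against independent brute-force summation to 1e-10.

## The synthetic cohort generator

The generator emulates the structure the pipeline assumes, not the optics
of the instrument:

- **Latent intent.** Per trial, one parameter (speed or stride) ramps
  monotonically 0.3 → 1.0 with smooth seeded jitter while the other holds
  at 0.65, mirroring a protocol in which subjects sweep one gait parameter
  per walk.
- **Hemoglobin.** Each channel sums five narrowband oscillators
  (amplitude-modulated sinusoids with slow random phase drift, centered at
  each band's geometric-mean frequency), plus linear drift and white noise.
  In informative channels (default 3 of 6) the oscillator amplitude is
  `0.3 + coupling_gain × intensity`; elsewhere it is fixed at the mid-ramp
  level, so zero coupling erases the distinction. HbR couples with
  opposite sign to HbO (envelope proportional to `1.05 − intensity`, at
  half amplitude), and HbT = HbO + HbR exactly. Every band's driving
  intensity is a weighted mix of the two latent parameters: stride
  dominates the cardiac/respiratory bands (weight 0.7) and speed the
  neurogenic/endothelial bands (0.7), with the myogenic band balanced.
  The cross-loading on the fast bands is what makes both parameters
  recoverable by windowed statistics — an oscillation slower than the
  analysis window cannot reveal its amplitude within one window.
- **Gait.** Angular velocity and angle are burst trains (squared-sine
  bursts, one per cycle; cycle periods uniform on 0.9–1.3 s, the normal
  adult range), whose per-cycle peaks are affine in the latent intensities:
  50 + 250·x deg/s for speed, 20 + 50·x deg for stride — realistic knee
  magnitudes. Per-cycle analytic peaks and exhaustive sample maxima of the
  clean trace are stored as ground truth.
- **Individuals.** Each subject carries a log-normal multiplicative gain
  (sd 0.2) and a Gaussian additive offset, which is the minimal structure
  that makes Z-score normalization and per-subject adaptation meaningful.
- **Determinism.** One master seed; every stream derives from integer
  hashing of (seed, subject id, trial mode, stage), so cohorts are bitwise
  reproducible and any subject can be regenerated in isolation.

Defaults: 38 subjects (8 reserved for adaptation), 60 s trials, 10 Hz
fNIRS sampling (typical for continuous-wave instruments and comfortably
above twice the 2 Hz cardiac band edge), 100 Hz inertial sampling, 6
channels, coupling gain 1, drift 0.005 units/s, noise sd 0.08, inertial
noise 1 deg/s.

What the generator does **not** emulate: photon-transport optics, motion
artifacts, probe geometry, hemodynamic response functions, or nonstationary
physiology. Passing tests therefore demonstrate that the pipeline recovers
the statistical structure it assumes — coupled band amplitudes, staircase
targets, subject gains — not that it would achieve any particular accuracy
on real recordings.

## Problem sizes and runtime choices

The test suite and the acceptance script run at reduced but structurally
complete scales, chosen so a full run stays comfortable on one CPU: the
recovery check trains 4-fold cross-validation on a 12-subject cohort
(roughly 1,300 window rows per gait parameter) in about 2–3 minutes, and
the adaptation check reuses that fit for 10 additional synthetic
individuals. Unit tests use 2–4 subject cohorts and 10–30 s trials. These
sizes are the package's own testing choices; all of them are plain
configuration and scale up freely.

## Known limitations

- The LSTM and autoencoder are plain R implementations with matrix BLAS;
  they are deliberately small (tens of thousands of parameters) and not
  suited to cohorts orders of magnitude larger.
- The screen threshold 0.3 is applied to absolute correlation; with very
  short trials the sample correlation of pure noise can exceed it, so the
  embedded stage and harmonic-mean combination carry the burden of
  discarding such features.
- Early stopping on a small validation fold is noisy; the patience of 8
  epochs absorbs some of that noise but fold metrics still vary by fold.
- Relative RMSE weights errors at small staircase values more heavily;
  with targets bounded away from zero (by construction ≥ 50 deg/s and
  ≥ 20 deg) this is benign, but the metric would be unstable for targets
  approaching zero.
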