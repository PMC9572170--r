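---
title: "Methods: wearable digital phenotyping and relapse anomaly detection"
author: "relapsekit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: wearable digital phenotyping and relapse anomaly detection}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Psychotic-spectrum relapses are usually recognized only after symptoms
escalate. Consumer smartwatches record physiological correlates of the
autonomic and motor changes that precede and accompany a relapse:
triaxial acceleration and angular velocity at 20 Hz, an RR-interval
(inter-beat) stream read out at 5 Hz from a PPG sensor, step counts, and
a sleep diary. `relapsekit` implements the two analysis layers such a
monitoring study needs:

1. a **descriptive layer** -- 5-minute window features of movement and
   heart-rate variability (HRV), aggregated per subject and compared
   between patients and controls with nonparametric tests under
   false-discovery-rate control; and
2. a **detection layer** -- autoencoders trained only on a patient's
   normal days that flag relapse days by the Mahalanobis distance of
   their reconstruction-error vectors, optionally fused with an audio
   (interview-spectrogram) channel.

Because raw clinical recordings of this kind cannot be redistributed,
the package is organized around a synthetic-cohort generator with known
ground truth; every estimator and every protocol stage is validated
against that ground truth or against independent brute-force oracles.

## The synthetic cohort generator

### Raw-signal tier

Each subject has an epoch at local midnight of day 0; all times are
seconds since epoch and days are half-open intervals `[86400k, 86400(k+1))`.

The RR generator is the simplest model with the right spectral
structure: per beat,

```
RR(t) = baseline + A_LF sin(2*pi*0.1 t) + A_HF sin(2*pi*0.25 t) + AR(1) noise
```

with `baseline ~ 800 ms` (raised by 120 ms during sleep), LF and HF
amplitudes of order 30 and 20 ms, and an AR(1) residual (phi = 0.9,
innovation SD 15 ms). The 5 Hz readout repeats the latest beat value
until the next beat, reproducing the identical-consecutive-values
artifact the preprocessor must undo. Configurable artifact processes add
out-of-range readouts (`rr_outlier_rate`), stuck readouts
(`repeat_rate`) and recording gaps (`gap_rate`).

Motion is a circadian-gated two-state bout process: per second the
subject is quiescent or in an activity bout (Markov transitions with
mean bout length ~10 s while awake, near-zero bout probability during
sleep), and 20 Hz samples are Gaussian with the bout-dependent SD
(gravity on the accelerometer z-axis). Steps per minute are Poisson in
the number of active seconds.

Relapse windows (severity low/moderate/severe scaling an annotated
`anomaly_magnitude` by 0.5/1.0/1.5) lower the RR baseline and raise the
activity scale; a prodrome ramps linearly from zero to half the relapse
magnitude over the `prodrome_days` (default 21) before onset.

### Interval-feature tier

Cohort-scale statistics and the detection models consume 5-minute
interval features. Simulating 20 Hz raw streams for hundreds of
subject-days and re-extracting features would be orders of magnitude
beyond a single-CPU budget, so the generator also draws interval
features directly from the same subject parameterization: for each of
the 14 feature types the subject's mean aggregate is
`population mean + between-subject SD * z_j` and the within-subject
interval SD is `population SD * exp(0.2 u_j)` with standard-normal
subject effects `z_j, u_j`. Configured effect sizes shift patients'
`z_j` (for `<feature>_mean` keys) or `u_j` (for `<feature>_std` keys) by
the stated number of between-subject SDs, which makes the realized
standardized group difference equal the configured value up to sampling
noise (the suite checks a +-0.25 band on the mean over four 50+50
cohorts). Population centers and spreads follow the magnitudes a
wrist-worn PPG/IMU cohort produces (RR near 800 ms, LF share near 31%
of LF+HF, STE in (m/s^2)^2). LF and HF percentages are complementary by
construction and the LF/HF ratio is derived from them, so effects
configured on `hf_pct` or `lfhf_ratio` are folded onto the LF share
with the appropriate sign.

Relapses shift each interval feature by
`magnitude * severity multiplier * direction * within-subject SD`, with
a fixed direction vector expressing autonomic arousal (heart rate up,
RR and vagal markers down, motor variability up, watch compliance
slightly down). A magnitude of zero leaves relapse windows statistically
identical to clean ones, which anchors the null calibrations.

### Sessions

Interview sessions are spectrogram-domain only: a patient-specific
rank-8 non-negative template model (smooth 128-band spectral templates
times smooth 64-frame activations plus a noise floor) generates
128 x 64 slices; anomalous states mix the templates and raise the noise
floor proportionally to the anomaly magnitude. Session states follow
the 30-day pre-relapse rule (the physiological layer uses 21 days --
both windows are kept distinct throughout).

### What the generator does not emulate

Second-order statistics only: no PPG waveform shape, no heteroscedastic
sensor drift, no speech synthesis, no medication or circadian-phase
confounds. Passing tests demonstrate that the estimators and the
protocol recover structure that is present by construction; they do not
certify clinical performance on real cohorts.

## Preprocessing rules

* RR: 5 Hz readouts are collapsed to beat events by dropping identical
  consecutive values; values outside [300, 2000] ms are removed; an
  inter-beat time gap exceeding 1.75x the local median RR (11-beat
  rolling window) is declared a missed-pulse run and filled by linear
  interpolation between the flanking values (when the oversized readout
  itself equals the gap, it is a merged interval and is replaced
  together with the fill); the sequence is truncated to the beats whose
  cumulative time lies within the first 270 s (90% of the window) so
  windows are length-comparable; windows with fewer than 10 cleaned
  beats are rejected with a `sparse` flag. `pct_valid` is the in-range
  fraction of raw beats. The 1.75x threshold and the 10-beat floor are
  package choices, exposed as arguments.
* Motion: 5-minute windows are nominally 6000 samples; more than 50
  missing samples rejects the window; remaining gaps are filled by
  nearest-neighbour interpolation, the window is truncated to its first
  5940 samples (99%), and each axis is denoised by suppressing the two
  finest detail bands of a periodized orthogonal db4 wavelet transform.
  Classic universal soft-thresholding is available
  (`denoise_wavelet(mode = "soft")`), but the default removes the top
  octaves outright: the IMU's intrinsic noise lives there, and robust
  shrinkage thresholds treat isolated glitch spikes as signal and pass
  them through, whereas band suppression attenuates a one-sample spike
  by well over half while reproducing constants exactly (the transform
  itself reconstructs perfectly, which the suite asserts).
* State labels: a window is `sleep` iff its midpoint falls inside a
  diary episode, half-open, so a midpoint at the exact episode end is
  awake.
* Day tensors: 288 slots x 10 features (`ste_acc, ste_gyr, hr_mean,
  rr_mean, lf_pct, hf_pct, sd1, sin_t, cos_t, pct_valid`). Missing runs
  of up to 120 slots (10 h) are filled per feature with the median over
  the surrounding +-12 slots (day median fallback; the deterministic
  time-of-day sine/cosine are recomputed exactly); longer runs reject
  the day. Windows are non-overlapping and contiguous.

## Feature estimators

* **STE**: mean squared Euclidean norm of the 3-axis vector -- the mean
  convention makes it window-length invariant.
* **Lomb-Scargle**: the classical phase-shifted least-squares estimator
  for unevenly sampled series. The signal is mean-centered before
  evaluation (without centering the DC component leaks into the LF
  band); `center = FALSE` restores the literal formula. Grid: 1024
  linear points on [0.001, 0.5] Hz (a package choice). LF is
  [0.04, 0.15] Hz and HF [0.15, 0.40] Hz, integrated by the trapezoid
  rule and reported as percent of (LF + HF) plus their ratio, so
  `lf_pct + hf_pct = 100` identically.
* **Sample entropy**: `-log(A/B)` over Chebyshev template matches at
  lengths m+1 and m, self-matches excluded, both counts over the n - m
  templates whose extended vector exists. Defaults m = 2, r = 0.2 SD
  (HRV literature convention; both in `feature_config()`).
* **Higuchi**: offset-averaged curve lengths L(k) for k = 1..10, least
  squares of log L(k) on log(1/k); ~1 for smooth curves, ~2 for white
  noise.
* **Multiscale fractal dimension**: flat morphological
  dilations/erosions of the signal graph at half-widths s = 1..30
  (iterated elementary dilations); per 64-sample frame the cover area
  A(s) is the mean envelope over samples with full +-s support (which
  eliminates frame-edge bias: a straight line yields exactly D = 1 at
  every scale and frame), and the local dimension is 2 minus the
  least-squares slope of log A over a sliding 5-scale window. Estimates
  are clipped into the theoretical [1, 2] band; a flat cover (constant
  frame) is D = 1 by convention, not an error. Summaries: `fd1` (mean
  dimension at the smallest scale window), min/max/mean/std over the
  full D(s, t) profile by default, with an axis switch (`summary_axis`)
  because summarizing over time, scale or both are all defensible.
* **Poincare**: SD1 = RMSSD/sqrt(2) (the uncentered second moment of
  lag-1 differences -- the HRV convention, and the only definition that
  satisfies the RMSSD identity exactly); SD2 is the mean-centered
  population SD of `(rr[n+1] + rr[n])/sqrt(2)`.
* **Daily activity**: steps and diary sleep/wake ratio, using only days
  with at least 20 recorded hours.
* **Welch band peaks** (`welch_band_peaks()`): the fusion-branch HRV
  variant -- RR resampled to a uniform 4 Hz grid, Hann-windowed 50%
  overlapping segments periodogram-averaged, peak power per LF/HF band.
  Both spectral variants (Lomb-Scargle normalized energies and Welch
  peaks) are exposed so either can feed the hourly 5 x 30 tensors.

## Group statistics

Per subject and sleep/awake state, the mean and SD of each of the 14
feature types give 28 aggregates. Groups are compared feature-wise with
two-tailed Mann-Whitney U tests (exact null distribution up to combined
n = 12 without ties, tie-corrected normal approximation otherwise,
delegated to `stats::wilcox.test`), medians and Q3 - Q1 IQRs with
linear-interpolation quantiles, and Benjamini-Hochberg adjustment over
all 28 features of one state run (`stats::p.adjust`). Steps and
sleep-ratio tests are adjusted separately, mirroring how such analyses
report them; both family choices are available. The recorded-data
balance check uses Student's t when both groups pass Shapiro-Wilk
normality at 0.05 and the Mann-Whitney fallback otherwise.

On null cohorts the comparison is calibrated: the suite checks that 20
null seeds yield zero BH-significant features in at least 95% of seeds.
A caveat the suite makes explicit: detecting a +1 between-subject-SD
shift on a single aggregate among 28 BH-adjusted features at 20+20
subjects requires a raw two-sided p below roughly 0.05/28, and a rank
test on a 1-SD shift (AUC about 0.76) reaches that threshold in well
under half of cohorts of this size. The corresponding acceptance check
therefore documents the measured detection rate rather than a
comfortable margin; a shift of that size at this sample size is simply
not reliably detectable under FDR control, which is itself a finding a
study at this scale should plan around.

## Anomaly models

No deep-learning framework is available to R in this project's
toolchain, so the package carries a compact reverse-mode automatic
differentiation engine (`R/nn-engine.R`, `R/nn-layers.R`): a tape of
value nodes with backward closures, dense/conv1d/conv2d layers via
cached im2col index maps, batch/layer normalization, max-pooling,
nearest upsampling, GRU cells, softmax attention, and Adam/RMSprop.
Every architecture is gradient-checked against central differences in
the suite (with biases perturbed off the ReLU kinks, where one-sided
subgradients make finite differences disagree by construction).

Architectures (widths in `model_config()`, never hard-coded):

* **FNN**: two dense encoder and decoder layers (64 -> 32 latent),
  ReLU, dropout before the output layer.
* **CNN**: four 1-D conv downsampling blocks (stride 2, kernel 5,
  filters 32/64/128/256) with batch norm and LeakyReLU, mirrored by
  four upsampling blocks and a final per-step linear map.
* **GRU**: seq2seq with hidden size 100 and dot-product attention over
  the encoder states feeding each decoder step.
* **Transformer**: input projection + sinusoidal positional encoding,
  four encoder layers (self-attention + feed-forward, layer norms,
  residuals), sequence reversal, four decoder layers of the same form,
  final linear map.
* **CAE / CVAE** (128 x 64 spectrogram slices): four conv blocks
  (kernel 3, filters 16/32/64/128, ReLU, 2x2 max-pool); the CVAE
  replaces the last block by parallel mu / log-variance heads (latent
  32 channels) with the reparameterization trick and a KL term to the
  spherical Gaussian.
* **1D-CVAE** (5 x 30 hourly HRV tensors): the 1-D adaptation of the
  same scheme.

Training: MSE loss (plus `W_KL = 0.01` times the KL for variational
models, `W_MSE = 1`); physiological models use batch 64, up to 50
epochs, learning rate 1e-4 (1e-3 for the transformer), Adam for
FNN/transformer, RMSprop for CNN/GRU; audio models use Adam 3e-4,
batch 8, up to 200 epochs, patience 10. Early stopping monitors the
first validation subset with patience 5 for the physiological models
(which run "up to 50 epochs with early stopping"); the best-validation
weights are restored. Every stochastic step (splits, initialization,
batching, latent sampling) is keyed from one run seed, and training is
bit-reproducible given that seed.

Scoring: the per-point mean absolute error between input and
reconstruction gives an error vector per time point (sequence models),
per mel band per slice (spectrogram models) or per feature per hour
tensor (1D-CVAE). The second validation subset provides the expected
error distribution (sample mean and covariance with a scaled-trace
ridge `1e-6 tr(Sigma)/d` for guaranteed invertibility -- scale
invariant, unlike an absolute ridge), and the anomaly score is the
squared Mahalanobis distance. Variational models additionally expose
the KL of the encoded posterior as a probe. The untrained baseline
applies the same Mahalanobis form to raw features.

## Evaluation protocol

Normal groups (days, or interview sessions) rotate through a 5-fold
split: per fold 60% train, 20% validation (halved into the
early-stopping and error-distribution subsets, sizes within one group
of each other) and 20% test; anomalous groups join every fold's test
set by default (switchable to partitioning, since distributing them is
equally defensible) and never reach training or normalization
statistics. Features are min-max normalized to [0, 1] with statistics
fit on the training partition only (per patient in `per_patient` mode),
the time-of-day sine/cosine passing through. A day is `relapse` when it
overlaps an annotated window; near-relapse days (21-day rule) are
discarded from training and testing alike. Scores are day-averaged;
ROC-AUC uses the rank (Mann-Whitney) identity and PR-AUC
interpolation-free step integration with the base rate recorded
alongside. Fold metrics are summarized by medians. Decision-level
fusion min-max standardizes each modality over the evaluation set (so
additive and multiplicative fusion act on commensurate scales -- the
standardization choice is the package's) before combining day-aligned
session and physiological scores; unpaired sessions are dropped and
counted.

Sub-sequences of the day tensor default to 48 slots (4 h); pooling over
per-slice scores supports average, max and norm pooling (p = 10), which
satisfy AP <= NP <= MP on non-negative scores.

## Problem sizes used in validation

The suite and the acceptance checks run at desk scale, chosen once as
realistic smallest-sizes that still exercise every code path: signal
batteries of length 1000; oracle comparisons at n = 30-300; calibration
cohorts of 20+20 subjects x 1 day at 5-minute resolution over 20 seeds;
detection cohorts of 10 patients x 45 days with 5-day relapses at
anomaly magnitude 2.0 (and a magnitude-0 replica for the null), the
personalized CNN trained per patient and fold with a 30-epoch budget
(early stopping normally halts well before it); ordering/fusion checks
over 20 seeds with the model-free Mahalanobis scorer, whose cheapness
lets the qualitative structure be probed across many seeds. The fusion
check runs 100 monitored days with session anomaly magnitude 0.15
(scored on 16-band spectral profiles -- coarser 8-band averages are
insensitive to the template-mixing perturbation, whose marginal effect
is to make slices *more* average) and physiological magnitude 0.7,
calibrated once so that each modality alone is only weakly informative
(day-level AUC in the 0.6-0.7 range) with independent noise -- the
regime where decision-level fusion has something to add.

## Known limitations

* The generator is a second-order emulation; its effect directions are
  stylized, and real relapse signatures are heterogeneous across
  patients.
* The NN engine is single-threaded R; it is adequate for the tensor
  sizes here but not for larger corpora.
* Batch normalization uses running statistics for evaluation; scoring
  is therefore independent of test-batch composition only after
  training has populated them, which the training loop guarantees.
* Exact BH-family membership (whether steps/sleep aggregates join the
  28) is study-specific; both modes are supported and the default
  adjusts them separately.
* The audio channel is spectrogram-domain only; no diarization is
  performed upstream.
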