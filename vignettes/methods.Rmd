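---
title: "Cross-modal speech-EEG fusion: models, assumptions and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cross-modal speech-EEG fusion: models, assumptions and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

# The problem

Alzheimer's disease (AD) and its prodromal stage, mild cognitive impairment
(MCI), alter both language production and resting-state cortical dynamics.
Speech is cheap to collect at scale; EEG carries physiological information
that speech lacks, but clinical EEG corpora rarely contain MCI recordings
and are rarely paired with speech from the same subjects.  `flowfuse`
implements a pipeline for the resulting asymmetric setting: three-class
(AD / MCI / HC) classification from speech, with EEG available only as an
unpaired AD/HC auxiliary cohort.

The pipeline has five stages:

1. **EEG biomarker extraction** — handcrafted descriptors per recording;
2. **dimensionality reduction** — PCA at a cumulative explained-variance
   threshold, or a masked autoencoder (MAE);
3. **cross-modal alignment** — two encoders map speech and EEG features
   into one 128-dimensional subspace, trained with a weighted
   cross-entropy classifier, a center loss, a cross-modal consistency
   loss and a domain-adversarial loss behind a gradient reversal layer
   (GRL), plus pseudo-MCI interpolation;
4. **conditional rectified flow** — a velocity-field network learns to
   transport Gaussian noise to aligned EEG latents conditioned on aligned
   speech latents, sampled with a 10-step Euler integrator;
5. **fusion classification** — a two-branch network with
   squeeze-and-excitation (SE) channel attention combines aligned speech
   features with the generated EEG-like latents.

# EEG biomarkers

All extractors consume an `eeg_recording` (channels x samples, µV,
sampling rate) and return one tibble row of named features.

**Time domain.** Mean, peak (maximum absolute amplitude), population
variance and SD, sample skewness, excess kurtosis (both defined as 0 for a
constant channel) and RMS, stacked feature-major: all means first, then all
peaks, and so on.  19 channels x 7 statistics = 133 values.

**Frequency domain.** The PSD is estimated by Welch's method (2 s Hann
windows, 50% overlap, one-sided density scaling); band powers are
rectangular bin integrals over the half-open clinical bands delta
[0.5, 4), theta [4, 8), alpha [8, 13), beta [13, 30) and gamma
[30, 100) Hz, with the gamma upper edge capped at the Nyquist frequency
(for a 95 Hz-limited or 45 Hz-limited recording the gamma band is
effectively truncated accordingly — this is documented behaviour, not an
error).  Per channel we report the five relative powers, the theta/alpha
and delta/alpha absolute-power ratios, the (delta+theta)/(alpha+beta)
low-to-high ratio, the median frequency (smallest frequency at which the
cumulative PSD over the analyzed 0.5 Hz-to-cap range reaches half its
total) and the normalized spectral entropy (Shannon entropy of the
normalized PSD bins divided by log K).  10 values x 19 channels = 190.
Band ratios use the same Welch PSD as the relative powers.  Zero
denominators are guarded by a small epsilon and flagged with a warning.

**Time-frequency.** A five-level discrete wavelet transform with the db4
mother wavelet yields sub-bands A5, D5...D1.  We use the orthonormal
periodized pyramid, so the sub-band energies sum exactly to the signal
energy — the invariant the test suite asserts.  Per sub-band: energy,
population SD of the coefficients, and Shannon entropy of the normalized
squared coefficients (0·log 0 = 0; an all-zero sub-band has entropy 0 by
convention).  18 values x 19 channels = 342.

**Multiscale entropy.** Coarse-graining replaces non-overlapping windows
of length τ by their means (output length ⌊N/τ⌋); sample entropy of each
coarse-grained series is −ln(A/B), counting unordered template pairs
within Chebyshev distance strictly less than r, self-matches excluded,
with templates restricted to the N − m extendable windows.  The tolerance
is fixed per channel at r = 0.15 x SD of the original series, which makes
the feature invariant to affine rescaling of the signal.  Scales 1..20,
embedding m = 2: 20 x 19 = 380 values.  Coarse-graining is the only
downsampling applied.  The pair counting is implemented in C++ (Rcpp); a
naive pure-R counter serves as the test oracle.

**Connectivity.** Each channel is band-pass filtered to the alpha band by
a zero-phase FIR filter of order ≈ 3·fs/f_low, the instantaneous phase is
taken from the FFT analytic signal, and the phase lag index
PLI(i,j) = |⟨sign sin(φ_i − φ_j)⟩| is computed after discarding one
filter length at each edge.  PLI is invariant to per-channel amplitude
scaling and is exactly 0 for identical channels.  The 19 electrodes are
grouped into five standard 10-20 regions (Frontal, Central, Temporal,
Parietal, Occipital); connectivity strength is the mean PLI over all
cross-region electrode pairs, one value per unordered region pair = 10
features.

# Dimensionality reduction

`pca_fit()` retains the smallest k whose cumulative explained-variance
ratio reaches the threshold (default 95%).  `mae_train()` implements the
masked autoencoder: 256-unit encoder and decoder with batch
normalization, ReLU and dropout 0.2; per-batch entry-level Bernoulli
masks at ratio 0.3 (mask granularity is per entry because the inputs are
flat vectors); masked entries are zero-filled at the encoder input; the
reconstruction loss is computed **only** on masked entries; Adam with
weight decay 1e-4; early stopping on a 10% validation split with
patience 5.  The decoder reconstructs all positions but only masked ones
are scored.

# Cross-modal alignment

Each modality has a two-layer encoder (first layer 256 units for speech;
64 units for EEG inputs up to 64 dims, 512 above that; batch norm + ReLU
+ dropout 0.2 between layers) into the shared 128-dim subspace.  The
training objective is the exact weighted sum

L_total = L_cls + 0.05·L_center + 0.1·L_domain + 5.0·L_consist

logged per epoch; the identity is asserted in the tests.

* **L_cls**: cross-entropy with per-class weights 1/proportion
  (proportions from the speech training fold), normalized by the batch
  weight sum, over speech, EEG and pseudo-MCI latents.
* **L_center**: mean (first-power) Euclidean distance of latents to their
  class centers.  Centers are updated by a separate SGD optimizer
  (lr 0.5) on the unweighted center loss, so the center gradient never
  competes with the encoder's main objective.
* **L_domain**: binary cross-entropy of a 128→64→1 discriminator fed
  through the GRL, whose factor ramps linearly from 0 to 0.1 over
  training (a sigmoidal DANN-style ramp is available by config).  The
  encoders receive the reversed, scaled gradient.
* **L_consist**: for every class present in both modality batches
  (MCI is always masked), the MSE between the speech and EEG class-mean
  latents, averaged over such classes; 0 when no class overlaps.

**Pseudo-MCI interpolation.**  Within each batch, same-batch AD and HC
latents (pooled over modalities) are paired at random and combined as
α·z_AD + (1−α)·z_HC with α ~ Beta(2, 2) (symmetric,
interior-concentrated; the Beta parameters are configurable because no
canonical value exists).  The interpolated anchors act as spatial
regularization: they enter the classification loss with label MCI and
the center loss toward the MCI center, both at weight 0.5.  Both
couplings can be disabled by config.

**Batching.** Speech is the primary modality: every epoch covers each
speech row exactly once in shuffled batches of 64.  EEG cycles through an
independent iterator that reshuffles whenever exhausted, so no EEG row is
starved.  Adam, lr 0.001 halved every 30 epochs, L2 decay 0.001,
200 epochs.

# Conditional rectified flow

The velocity network receives the flow state x_t, the scalar time
t ∈ [0, 1] and the condition c (an aligned speech latent).  t and c pass
through independent two-layer SiLU embeddings to width 256, x_t through a
linear projection; the three are summed, pass through three residual
blocks (two SiLU dense layers each, post-residual layer normalization)
and a linear head back to the state dimension.  The time input is the
plain scalar (no sinusoidal embedding).

Training constructs straight paths x_t = t·x1 + (1−t)·x0 with
x0 ~ N(0, I), t ~ U(0, 1), and minimizes the flow-matching loss — the
mean squared error between the predicted velocity and the constant path
derivative x1 − x0, averaged over batch **and** dimensions (multiply by
the state dimension to convert to the summed-squared-norm convention).
Each training pair takes x1 as an aligned EEG latent and c as an aligned
speech latent of the same class, re-matched at random every epoch; no
canonical pairing rule exists for unpaired cohorts, so random same-class
matching is the weakest assumption consistent with the class structure.
Sampling integrates dx/dt = v(x, t, c) with N = 10 uniform Euler steps
x_{k+1} = x_k + (1/N)·v(x_k, k/N, c).  A constant field makes the
integrator exact for any N (telescoping), which the tests exploit.
State and condition both live in the 128-dim aligned subspace by default
(consistent with the fusion input; configurable).

# Fusion and evaluation

Each branch maps its input to 128 units (dense + batch norm + ReLU +
dropout 0.3); the concatenated 256-vector is reweighted by an SE module
(for flat vectors the squeeze over a singleton spatial axis is the
identity, so the gate is sigmoid(W2 ReLU(W1 f)) with bottleneck
256→32→256 at ratio 8) and classified by a 64-unit MLP head.  Adam with
L2 decay 1e-4, batch 16, early stopping patience 20 on a stratified
internal validation split, plateau-based learning-rate halving
(factor 0.5, patience 10).

Metrics use the one-vs-rest reduction of the 3x3 confusion matrix:
per-class sensitivity, specificity, precision and F1 (harmonic mean),
accuracy as trace/total, unweighted macro averages, and macro one-vs-rest
AUC from predicted probabilities.  Fractional (fold-averaged) confusion
matrices are supported.  Classes absent from the truth are excluded from
macro averages with a warning.  Cross-validation stratifies the speech
training set into five folds, keeps one fixed 4:1 EEG train/validation
split across folds, trains every stage from scratch per fold
(independent initialization, asserted by parameter fingerprints) and
aggregates mean ± SD per seed, then across seeds.

# The synthetic-data generator

`continuum_spec()` + `generate_continuum_cohort()` encode the structural
assumptions the method relies on, nothing more:

* a low-dimensional latent space (default 8) with HC and AD anchors at
  ∓1 on every coordinate and the MCI anchor at `mci_position` (default
  0.5 — the clinical literature gives no quantitative placement, so the
  midpoint is the neutral choice) on the HC→AD segment;
* affine maps (Gaussian, scale 1/√latent_dim, drawn once from the spec
  seed) into speech space (default 128 dims) and EEG space (default 32
  dims, matching the reduced EEG feature set the full pipeline uses);
* isotropic Gaussian feature noise, default SD 0.3 per modality
  (configurable per modality) — subjects sit exactly at their class
  anchor, so all within-class variation is observation noise and the
  class-mean targets are closed-form;
* EEG rows exist only for AD and HC.

`generate_band_structured_eeg()` produces multichannel signals as sums of
five sinusoidal carriers at 2/6/10/15/25 Hz (representative centre
frequencies of the five rhythms) with per-channel random phases plus
white noise; the AD-like profile elevates delta/theta and suppresses
alpha.  Per-channel draws use counter-based sub-seeds, so appending
channels never perturbs earlier ones.  The generator makes no attempt at
realistic EEG morphology (no spindles, artifacts or 1/f background);
passing tests therefore demonstrate correctness of the pipeline's
statistical machinery on data satisfying its assumptions, not clinical
performance.

# Numerical choices and problem sizes

* All networks run on an explicit dense-layer engine with hand-derived
  backward passes (dense, batch norm, layer norm, ReLU/SiLU/sigmoid,
  dropout, SE gate, residual blocks), verified against central finite
  differences in the test suite.  Batch-norm running statistics are
  refreshed from a full-data pass at the end of each epoch, which is
  cheaper and more stable than per-batch exponential updates at these
  cohort sizes.
* Degenerate inputs fail loudly: all-zero PSDs, constant series whose
  relative tolerance collapses, template counts of zero in sample
  entropy, dimension mismatches in every encoder.
* The validation-suite problem sizes are chosen for a single CPU: the
  parameter-recovery studies use cohorts of 200 subjects per class with
  the full 128/32-dim maps and the published training lengths for the
  alignment network (200 epochs), while the conditional flow is trained
  for 300 epochs there (its loss plateaus well before 500 on these
  cohorts) and the ablation harness uses 100 subjects per class with
  shortened alignment and fusion training (60 and 80 epochs) — the
  defaults keep the published settings.
* Class-mean recovery of the conditional flow is reported as the
  **per-dimension RMS** deviation of the generated class means from the
  true EEG class means, compared against half the generating noise SD.
  A raw Euclidean norm across 32 dimensions is not comparable to a
  scalar noise SD: even a perfect generator incurs a Euclidean
  Monte-Carlo error of ≈ noise_sd·√(d/n) from averaging n samples, which
  at n = 200, d = 32 nearly exhausts such a bound by itself.  The RMS
  form is the dimension-consistent reading and is what the acceptance
  script computes.
* The ablation study uses a speech-noisy / EEG-clean cohort
  (noise SD 2 vs 0.3).  That is the regime the EEG-informed pathway is
  designed for: the flow distils the clean EEG class geometry into a
  transform of the speech representation.  Note a structural property of
  any fully synthetic ablation: generated latents are functions of the
  speech input, so the fused model cannot exceed the Bayes accuracy of
  speech alone — gains over the align-only mode can only come from the
  regularizing, distillation-like effect of the EEG-trained flow, and are
  accordingly small on synthetic data.

# Known limitations

* No artifact rejection, re-referencing or ICA — inputs are assumed
  preprocessed.
* No PSD topographic image features or deep speech feature extractors;
  the pipeline consumes precomputed speech feature tables.
* The EDF reader covers uncompressed 16-bit EDF with a uniform record
  layout, which is sufficient for resting-state clinical exports.
* Training is plain R linear algebra: adequate for cohorts of hundreds
  of subjects and feature widths in the hundreds, not for raw-signal
  deep learning.
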