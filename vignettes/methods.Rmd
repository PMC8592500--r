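---
title: "Methods: adversarial synthesis of EEG spectrograms for seizure prediction"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: adversarial synthesis of EEG spectrograms for seizure prediction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Seizure-prediction classifiers are starved for labeled pre-ictal EEG: good
long-term recordings are rare, expensive, and dominated by interictal time.
One proposed remedy is to synthesize pre-ictal data with a generative
adversarial network and use it either in place of real data or to augment
it. `spectrogan` implements that whole experimental loop as a testable
framework: simulate EEG-like signals, turn them into spectrogram images,
train a DCGAN to synthesize pre-ictal samples, screen the samples with a
one-class SVM, train a small convolutional classifier (the "convolutional
epileptic seizure predictor", CESP) under the four train/test regimes
TRTR / TSTR / TRTS / TSTS, and score the result at the event level against
a chance-level alarm model.

Everything runs on synthetic data generated by the package itself, so the
pipeline is exercisable end to end on one CPU with no downloads. Real
recordings in EDF or any other format can be substituted anywhere a list of
`eeg_segment` objects is accepted.

## The synthetic EEG model

`sim_config()` describes a two-class signal model chosen to be the simplest
auditable generator with the statistical structure the pipeline assumes:

* a `1/f^alpha` background (shaped Gaussian noise, `alpha = 1` by default),
  the canonical broadband shape of EEG spectra;
* per-class narrow-band oscillators: each band `(center, bandwidth,
  amplitude)` contributes three sinusoids with frequencies drawn uniformly
  inside the band and random phases. The two classes differ *only* in their
  band sets (defaults: an "alpha-like" 10 Hz band for interictal and a
  "beta-like" 24 Hz band for pre-ictal, over a shared 6 Hz component);
* a mains sinusoid at 50 or 60 Hz with a segment-wide random phase;
* additive white noise.

Class structure therefore lives entirely in band power, which makes
separability measurable by construction (a linear classifier on band
log-power must succeed) and gives the GAN a concrete, inspectable target.
The generator makes no claim about the biology of pre-ictal dynamics: real
pre-ictal signatures are patient-specific, non-stationary and far subtler.
Passing tests on this fixture demonstrate that the *pipeline* behaves as
specified, not that the method would reach any particular performance on
clinical recordings.

Three presets mirror common acquisition settings: `"ieeg-like"` (16
channels, 400 Hz, 50 Hz mains, 10-minute segments), `"scalp-like"` (22
channels, 256 Hz, 60 Hz mains) and `"desk"` (8 channels, 256 Hz, 8-second
segments) for fast CPU experiments. Determinism is contractual: one seed
per dataset, per-segment sub-streams derived by counter, so segment `i` is
reproducible in isolation.

`simulate_timeline()` lays seizure onsets on a continuous timeline and
extracts labeled segments around them: pre-ictal segments from the window
spanning one seizure-occurrence period (SOP) and ending one
seizure-prediction horizon (SPH) before each onset, interictal segments at
least four hours away from every onset. Onset placement requires at least
4.5 hours before the first onset so that interictal time exists at all;
infeasible packings error out rather than silently degrade.

## Segments to images

`preprocess_dataset()` applies, per segment:

1. **Line-noise removal** — a zero-phase (forward-backward) Butterworth
   band-stop filter of order 4 per band, defaulting to the fundamental
   ± 3 Hz and first harmonic ± 3 Hz (i.e. 47–53 / 97–103 Hz for 50 Hz
   mains, 57–63 / 117–123 Hz for 60 Hz). Harmonic bands above Nyquist are
   skipped with a message.
2. **STFT** — Hann window, FFT length equal to the window length, phase
   discarded. The reference configuration is a 60 s window with no overlap,
   so a 10-minute segment yields 10 time columns.
3. **Assembly** — channel spectrograms are stacked along the frequency
   axis in channel order, `log(1 + m)` transformed, bilinearly resized to
   `S x S` (`S = 256` reference, `S = 64` desk), min-max normalized to
   `[-1, 1]`, and replicated to three identical channels.

The output shape is `(S, S, 3)` regardless of channel count or sampling
rate — that invariance is the point of the representation, since it makes
the generative model independent of the acquisition montage.

Choices the source architecture leaves open, fixed here and exposed in
`preprocess_config()`: the window function (Hann, the conventional STFT
default), the log transform (on by default; magnitudes span orders of
magnitude and saturate min-max normalization otherwise), normalization last
(after resize), bilinear interpolation, and the three-channel construction
(replication rather than a colormap, because replication is lossless with
respect to the single-channel content and keeps RGB-shaped networks
applicable). A constant image maps to −1 by convention. Normalizing to
`[-1, 1]` matches the generator's tanh output head.

## The DCGAN

The generator maps a 100-dimensional standard-Gaussian latent vector
through a dense layer of width 4096 reshaped to `4 x 4 x 256`, then six
stride-2 transposed convolutions (5×5 kernels, "same" padding; 256 filters
in the first layer and 128 in the rest), so the side doubles per layer:
`4 * 2^6 = 256`. Because the last transposed convolution still carries 128
channels, a final stride-1 5×5 convolution projects to 3 channels under a
tanh head — the common DCGAN output block, which the layer listing above
leaves implicit. Batch normalization follows every hidden layer. The
discriminator applies four stride-2 5×5 convolutions with 256/128/64/32
filters and leaky-ReLU activations into a single sigmoid score. The desk
configuration divides all filter counts by four and uses four deconvolution
stages (`4 * 2^4 = 64`).

Training alternates one discriminator and one generator step per batch
(batch 32, Adam with `beta1 = 0.5`, learning rate `1e-3`). The
discriminator minimizes binary cross-entropy with targets real = 1 /
fake = 0, equivalent up to sign and constant to maximizing the mini-max
value returned by `d_loss()`. The generator minimizes the non-saturating
loss `-(1/n) sum log D(G(z))` (`g_loss()`): the saturating form vanishes
early in training, and any form written in terms of real data alone has no
generator gradient — which is why the printed generator objective of the
source description, a function of `D(x)` only, is treated as a typo and
replaced by the non-saturating form.

**Early stopping.** Training stops when the discriminator loss exceeds the
generator loss for `k = 15` consecutive batches (the streak resets on any
compliant batch). The two losses are only comparable on a common scale: the
raw mini-max value contains two log terms against the generator loss's one,
so at the 0.5/0.5 equilibrium it would sit at twice the generator loss and
the rule would fire immediately. The recorded monitors are therefore the
discriminator's *mean* binary cross-entropy over the real and fake
half-batches and the generator's binary cross-entropy, which coincide at
equilibrium. `early_stop_index()` replays the rule over any recorded
history and is the oracle the training loop is tested against.

The network engine itself (dense, convolution, transposed convolution as
the convolution adjoint, max pooling, batch normalization, Adam, fused
sigmoid cross-entropy) is implemented in the package in R with
single-precision im2col/GEMM convolution kernels in C++. Every layer's
backward pass is validated against central finite differences in the test
suite. Weight initialization is normal with standard deviation 0.02
throughout the GAN, the common DCGAN recipe.

## One-class SVM screening

Generated samples are screened by a nu-one-class SVM with RBF kernel
trained on real pre-ictal images: samples on the positive side of the
decision function `sign(sum_i beta_i K(x_i, x) - rho)` are accepted, the
rest discarded. Features are the channel-mean image downsampled bilinearly
to 16×16 and flattened (256 dimensions). The coarse scale is deliberate:
at fine scales (32×32 and above) the RBF distance is dominated by pixel
texture, which a CPU-budget GAN never matches, and the screen rejects
everything; at 16×16 the distance reflects band-level spectral layout —
the content that carries class information here — and the screen passes
plausible samples while still rejecting far outliers. `nu` (default 0.1)
bounds the training-outlier fraction, a property the tests verify
empirically; `gamma` defaults to the `1/(d * var)` heuristic. None of
these values are prescribed by the reference description, which reports
only that the hyperparameters were selected experimentally.

## The CESP classifier

Three convolution blocks (3×3 kernels, stride 1, ReLU, 2×2 max pooling)
with 126, 64 and 64 filters — 126 kept as printed, not rounded to 128 —
followed by a 32-unit sigmoid layer and a 2-unit sigmoid output trained
with one-hot binary cross-entropy (two independent sigmoids, not a
softmax). Training uses Adam at `1e-4` for the reference configuration;
the desk experiments use `1e-3` because at desk problem sizes (a few
hundred images, a few dozen optimizer steps) the reference rate has not
begun to converge within the step budget. `train_cesp()` performs
stratified 10-fold cross-validation (90/10 splits), records per-fold
validation accuracy, then refits on the full training split — the
reference procedure reports the cross-validation but not how the deployed
model is obtained, so refitting is this package's choice. The pre-ictal
unit's raw sigmoid score is the ranking statistic; `predict_cesp()` also
returns the pairwise-normalized score `p1 / (p0 + p1)`, which is the
better-calibrated quantity for fixed-threshold alarms (a model trained on
synthetic data ranks real test data correctly long before its absolute
scores are calibrated).

## Evaluation protocol

`run_regime_matrix()` trains and tests the CESP under the four
combinations of real and synthetic sources. Test partitions are
time-disjoint from training — the split is on `t_start`, the latest
quarter of the timeline held out — and shared across regimes with the same
test source; one model is fitted per training source. When the synthetic
set carries only the pre-ictal class (the augmentation scenario), its
interictal side is completed with real training-partition images and the
training set is balanced by upsampling the minority class with
replacement.

Event-level scoring follows the standard SPH/SOP alarm semantics: an alarm
at time `t` predicts a seizure with onset `o` iff `t + SPH <= o <= t + SPH
+ SOP` (defaults SPH = 10 min, SOP = 30 min). Alarms are subject to a
refractory period of one SOP. Two boundary conventions are fixed here
because the reference definitions leave them open: an alarm closer to an
onset than the SPH counts as a false alarm (it failed the required lead
time), and the interictal-hours denominator of FPR/h excludes the
`(onset - SPH - SOP, onset]` windows.

The chance-level comparison uses the random-predictor model: a Poisson
alarm process at the observed FPR raises at least one alarm in an SOP with
probability `P = 1 - exp(-FPR * SOP)` (SOP converted to hours), and the
probability of predicting at least `n` of `N` independent seizures by
chance is the binomial tail `sum_{k>=n} C(N,k) P^k (1-P)^{N-k}`, computed
with log binomial coefficients. The tests check this against both direct
enumeration and a Monte-Carlo tail. AUC comparisons between predictors use
the single-tailed Hanley–McNeil z-test in its independent-samples form
(the correlated-ROC variant needs a correlation estimate that is not
available here), with a Bonferroni-adjusted level for multiple
comparisons.

Whether tabulated sensitivities in this literature are segment-level or
event-level is often ambiguous; the package computes and reports both
(`segment_metrics()` vs `alarm_evaluate()`).

## Problem sizes and numerical choices

The package's own reference experiment (mirrored by
`scripts/acceptance.R` and the end-to-end test) uses the desk preset: 200
segments per class, 64×64 images, a quarter-scale DCGAN trained for up to
40 epochs at batch 32, 200 generated samples screened by the selector,
CESP training at `1e-3` for 5 epochs, and a 10-hour timeline with 4
seizures for alarm scoring. These sizes were chosen so the whole loop runs
in well under half an hour on one CPU while every qualitative property of
interest (classifier separation, generator learning, selector acceptance,
better-than-chance alarms) is measurable. Full-scale 256×256 training at
thousands of epochs — days of GPU time in the reference setting — is out
of scope, and the headline clinical numbers of that setting (sensitivities
near 80–88%, FPR/h near 0.14–0.27) are not reproducible from simulated
data; no test asserts them.

Numerical conventions: probabilities are clamped at `1e-7` before
logarithms; batch-norm uses `eps = 1e-5` and momentum 0.99 for running
statistics; constant images normalize to −1; the empty selection has
acceptance rate 0 by convention; non-finite GAN losses abort training with
the epoch/batch state in the message.

## Known limitations

* The conv-net engine is single-precision and single-threaded; it is meant
  for desk-scale experiments and correctness, not throughput.
* The simulator omits artifacts (blinks, EMG), circadian structure and any
  physiologic seizure morphology; conclusions about real EEG require real
  EEG.
* EDF import/export is not included; adapt real recordings to
  `eeg_segment` lists with existing EEG tooling.
* The Hanley–McNeil test assumes independent samples; comparing two models
  evaluated on the same test set violates that assumption conservatively.
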