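---
title: "Methods: voice biomarkers, contrastive embeddings, and fused classification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: voice biomarkers, contrastive embeddings, and fused classification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(voxfuse)
```

voxfuse implements a multi-modal screening pipeline for Parkinson's disease
(PD) from voice: perturbation-based acoustic biomarkers extracted from
sustained phonation, self-supervised utterance embeddings trained with a
contrastive objective, and a residual-attention neural classifier that fuses
both modalities. This vignette documents the mathematical model behind each
stage, the fixed study parameters, what the synthetic-phonation generator
does and does not cover, the numerical choices that matter for
reproducibility, and the limitations of the toolkit.

## 1. Signal model and preprocessing

A recording is a `waveform` record: a numeric sample vector plus a sampling
rate (16 kHz throughout). Preprocessing (`preprocess()`) runs four steps:

1. **Resampling** to 16 kHz via polyphase filtering (`signal::resample`).
2. **Voice activity detection**: short-time log-energy (25 ms frames,
   10 ms hop) thresholded at a fixed offset above the estimated noise
   floor; the longest voiced run is retained.
3. **Spectral gating**: an STFT magnitude gate that attenuates
   time-frequency bins below a per-band noise-floor estimate taken from
   the unvoiced regions, with smooth attenuation rather than hard zeroing.
4. **Duration/level normalization**: pad or trim to a fixed length and
   standardize to zero mean, unit population variance.

## 2. Acoustic biomarkers

Cycle marks come from a peak-picking walk: after an autocorrelation-based
global period estimate, each next peak is searched inside a window of
0.7–1.3 times the running period, with parabolic refinement of peak
positions (the true extremum generally falls between samples). From the
period sequence $p_1,\dots,p_N$ and per-cycle peak-to-trough amplitudes
$A_1,\dots,A_N$:

- **Local jitter (%)**: $\frac{\frac{1}{N-1}\sum |p_{i+1}-p_i|}{\bar p}
  \times 100$, plus absolute jitter, RAP (3-point) and PPQ5 (5-point)
  smoothed quotients.
- **Local shimmer**: the analogous relative quotient on $A_i$, plus dB
  shimmer $\frac{1}{N-1}\sum |20\log_{10}(A_{i+1}/A_i)|$ and APQ3.
- **HNR**: from the normalized autocorrelation $r$ at the pitch-period
  lag, $\mathrm{HNR} = 10\log_{10}\frac{r}{1-r}$ dB, averaged over 80 ms
  frames; $r$ is clamped away from $\{0, 1\}$ before the log.
- **MFCCs**: 26 mel triangular filters between 0 and Nyquist; coefficient
  $k$ of a frame with log filterbank energies $\log S_n$ is
  $c_k = \sum_{n=1}^{M} \log S_n \cos\!\big(\frac{\pi k}{M}(n - \tfrac12)\big)$,
  averaged over frames. A flat spectrum yields exactly zero for all
  $k \ge 1$ (the DCT basis vectors are zero-mean).

The default biomarker vector has 22 entries (`default_feature_schema()`):
F0 statistics, five jitter measures, four shimmer measures, HNR, and 13
MFCC means collapsed to the schema's summary set.

## 3. Contrastive utterance embeddings

The encoder is a small 1-D convolutional network (total stride 320, i.e.
about 50 token vectors per second at 16 kHz) followed by mean pooling and
a projection head. Pretraining minimizes NT-Xent: for a batch of $N$
utterances, two stochastic augmentations (gain, noise, time shift,
time-masking) of each produce $2N$ views; with cosine similarities
$s_{ij}$ and temperature $\tau = 0.07$,

$$\ell_i = -\log \frac{\exp(s_{i,\mathrm{pos}(i)}/\tau)}
 {\sum_{k \ne i} \exp(s_{ik}/\tau)}, \qquad
 L = \frac{1}{2N}\sum_{i=1}^{2N} \ell_i.$$

The implementation is vectorized but verified against a literal
double-loop oracle to $10^{-8}$; gradients are analytic and checked by
finite differences. With $N = 1$ there are no negatives and the loss is
exactly zero. After pretraining, an utterance embedding is the mean-pooled
encoder output (32 dimensions by default).

## 4. Fused classifier

The input is the concatenation of the standardized biomarker vector and
the embedding. Two residual blocks precede the head:

- **Block A**: two dense+ReLU+dropout layers with batch normalization,
  plus a linear skip projection $P$ added to the block output.
- **Block B**: a post-layer-norm transformer-style block (multi-head
  self-attention over learned tokens, then a feed-forward sublayer), with
  the whole block wrapped in one residual connection.
- **Head**: dense → ReLU → batch norm → dropout → dense → softmax over
  {control, PD}.

All layers are hand-rolled with analytic backpropagation (verified against
central finite differences at $10^{-4}$ relative tolerance). Batch
normalization uses population variance with $\epsilon = 10^{-5}$ and
running statistics updated only in training mode; evaluation mode is fully
deterministic.

## 5. Training protocol

Adam ($\beta_1 = 0.9$, $\beta_2 = 0.999$, $\epsilon = 10^{-8}$) with
weight decay $10^{-4}$, batch size 32, and cosine annealing

$$\eta_t = \eta_\min + \tfrac12(\eta_\max - \eta_\min)
  \big(1 + \cos(\pi t / T)\big)$$

with $\eta_\max = 10^{-4}$, $\eta_\min = 10^{-6}$, $T = 100$ epochs. The
endpoints are exact in double precision: $\eta_0 = \eta_\max$ and
$\eta_T = \eta_\min$ bit-for-bit. Early stopping monitors validation loss
(patience 10, minimum delta $10^{-5}$) and restores the best checkpoint.
Feature-noise augmentation adds Gaussian noise at 5% of each feature's
training-set range. Splits are **subject-wise** (70/15/15): all samples of
one subject land in one subset, preventing identity leakage; the plan
carries a content hash and is re-validated before training and evaluation.

## 6. Attribution

- **MDI**: a random-forest surrogate's normalized Gini
  mean-decrease-in-impurity per feature.
- **Shapley**: permutation-sampling attribution for a single prediction.
  Each Monte-Carlo draw walks from a background row to the explained
  sample one feature at a time; summed credits telescope exactly, so
  attributions plus the mean-background baseline reproduce the model
  output up to floating-point error (local accuracy). For a linear model
  $f(x) = w^\top x$ the attributions converge to
  $w_i (x_i - \mathbb{E}[x_i])$.
- **Confidence reports** summarize class-conditional PD-probability
  distributions and their histogram overlap.

## 7. Synthetic-phonation generator: scope

`generate_phonation()` synthesizes a band-limited sawtooth voice source
with per-cycle multiplicative perturbations: period $p_i = \bar p\,
\varepsilon_i$ and amplitude $A_i = \bar A\, \delta_i$ with
$\varepsilon_i, \delta_i \sim \mathcal N(1, \sigma)$, plus white noise
scaled by exact RMS to hit a target HNR. Crucially it returns the
**realized** per-cycle sequences (`truth`), so estimator accuracy is
judged against what was actually synthesized, not the nominal parameters
(`oracle_perturbation()` computes the reference quotients from the truth).
The generator covers phonatory instability only: it does not model
formants, breathiness spectra, tremor, articulation, or prosody, and
cohort-level class differences are injected parametrically. Results on
synthetic cohorts validate the *software*, not clinical performance.

## 8. Numerical choices

- All randomness flows from one seed through named substreams
  (`seed_substream`), so any stage is reproducible in isolation.
- Peak amplitudes use parabolic interpolation; grid-sampled extrema would
  inject artificial cycle-to-cycle amplitude noise comparable to small
  shimmer levels.
- Cycle marking is clamped to the span where signal energy exceeds 1% of
  the segment peak, so boundary frames never pick peaks from the noise
  floor.
- Softmax cross-entropy floors probabilities at $10^{-12}$ before the
  log; HNR clamps $r$ before the log-ratio.
- ROC AUC is the tie-aware normalized Mann–Whitney statistic (constant
  scores give exactly 0.5).

## 9. Limitations

- Synthetic cohorts are far easier than clinical voice data; accuracy
  numbers here are software checks, not clinical claims.
- The encoder is deliberately small (CPU-friendly); it demonstrates the
  contrastive objective rather than a state-of-the-art speech model.
- Biomarker extraction assumes sustained phonation with a reasonably
  stable F0 in 75–500 Hz; running speech is out of scope.
- Single-machine, single-thread: no GPU paths, no distributed training.
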