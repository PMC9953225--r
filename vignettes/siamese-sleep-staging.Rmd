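---
title: "Siamese-network sleep staging: model, losses and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Siamese-network sleep staging: model, losses and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Clinical sleep scoring assigns each 30-second epoch of an overnight EEG
recording to one of five stages — wake (W), the three non-REM depth grades
N1–N3, and REM. `sleepsiam` implements an automatic stager for
single-channel EEG built around a *Siamese* encoder: two applications of
one shared-parameter network map a pair of epochs into a latent space where
same-stage pairs are pulled together and different-stage pairs are pushed
apart. The latent feature of each epoch is then concatenated with the raw
epoch and classified by a CNN + sequence model.

## Model and losses

Let $G_W$ be the shared encoder. For an epoch pair $(x_1, x_2)$ the latent
distance is the Euclidean distance of the encodings,
$D_W(x_1,x_2) = \lVert G_W(x_1) - G_W(x_2)\rVert_2$. The contrastive loss of
a batch of $P$ pairs is the **sum** (not the mean) of the per-pair terms

$$
\ell(x_1,x_2) \;=\;
\begin{cases}
\tfrac12 D_W^2 & \text{same stage},\\[2pt]
\tfrac12 \max(0,\, m - D_W)^2 & \text{different stage},
\end{cases}
$$

with margin $m > 0$. The two branches meet continuously at $D_W = m$; a
dissimilar pair at zero distance costs $m^2/2$, and one beyond the margin
costs nothing. Because the aggregation is a sum, the batch size enters the
loss scale; this is deliberate and documented rather than normalized away.

A note on the label convention: descriptions of this loss sometimes attach
$y = 1$ to *similar* pairs, which — substituted literally into the formula
above — would put same-stage pairs on the margin branch and contradict the
stated objective (similar pairs should have *small* distance). The package
follows the objective: the margin branch applies to different-stage pairs,
matching the canonical contrastive-loss formulation in which the indicator
marks dissimilarity.

Classification uses the usual multi-class cross-entropy, averaged over
epochs, with true-class probabilities clamped at $10^{-12}$.

The autoencoder variant adds a reconstruction distance between the batch of
input epochs $u$ and the batch of decoder outputs $v$:

$$
D(u, v) \;=\; \lVert u - v\rVert_2 \;+\; \widetilde{\max W_2}(u, v),
$$

where the Euclidean term is the per-epoch distance averaged over the batch
and $\widetilde{\max W_2}$ is the **max-sliced Wasserstein-2 distance**: the
largest 1-D $W_2$ obtainable by projecting both point sets onto a single
unit direction $\omega$. With equal sample counts the 1-D $W_2$ has a closed
form — the root-mean-square difference of the sorted projections (the
optimal monotone coupling). Reading "the two distributions" as *the batch
of epochs versus the batch of reconstructions* (each epoch a point in
$\mathbb{R}^{f_s \cdot 30}$) is the standard interpretation in sliced-
Wasserstein training; a single epoch would give a one-point "distribution"
and a degenerate distance, so batches of fewer than two epochs fall back to
the 1-D $W_2$ over the two vectors' samples (logged).

The composite losses are
$\mathcal{L}_{\mathrm{CNN}} = \mathrm{CE} + \mathrm{CT}$ and
$\mathcal{L}_{\mathrm{AE}} = D(\text{epoch}, \text{reconstruction}) +
\mathrm{CE} + \mathrm{CT}$. The cross-entropy is a mean while the
contrastive term is a sum; the resulting scale asymmetry is implemented
exactly as the definitions read.

### Maximizing over directions

No closed form exists for the maximizing direction, so `max_sliced_w2()`
searches: the best of `n_directions` random unit vectors (drawn
sequentially, so enlarging the candidate set under one seed can only raise
the result), then `n_refine` projected gradient-ascent steps with
backtracking, always keeping the best direction seen. The gradient holds
the two sort permutations fixed, which is exact almost everywhere. The
search is one-sided by construction — it can only under-estimate the true
supremum — and tests verify it against dense direction grids (within 1%)
and the translation identity $\widetilde{\max W_2}(u, u+t) = \lVert t
\rVert_2$. Defaults are 64 directions + 50 refinement steps; the tiny test
profile uses 8 + 5, where the training signal does not require a tight
maximum, only a consistent ascent direction.

## Architectures

Both Siamese variants share their parameters across the two branch
applications *structurally*: there is exactly one parameter set, and
"either branch" is the same function. Gradients from both applications
accumulate into that single set, so sharing cannot drift apart during
training.

* **Siamese AE** — encoder: three 1-D convolution stages (kernel 8, stride
  2, filters 32→64→64, each with batch normalization and ReLU), flattened
  and projected linearly to a `latent_dim`-dimensional feature (default
  128). The decoder mirrors the encoder with transposed convolutions
  (stride 2) and a final trim/pad to exactly $f_s \times 30$ samples —
  3000 at 100 Hz, 7680 at 256 Hz. The exact printed layer geometry of the
  original architecture diagrams is not recoverable from text, so this
  minimal mirrored three-stage design is adopted and config-exposed.
* **Siamese CNN** — a two-branch convolutional stack in the DeepSleepNet
  lineage: a small-filter branch (first kernel $f_s/2$, stride $f_s/16$)
  for temporal detail and a large-filter branch (first kernel $4 f_s$,
  stride $f_s/2$) for frequency content, each continuing with three padded
  kernel-8 convolutions, max-pooling and dropout 0.5, concatenated and
  projected to the latent dimension.
* **Staging model** — the same two-branch CNN geometry over the *augmented*
  input (raw samples followed by the latent vector; vector concatenation,
  since channel-stacking would require equal lengths), a linear softmax
  head over the five stages, and a sequence residual block used at
  finetuning: two bidirectional LSTM layers (hidden 512 per direction,
  forget-gate bias initialized at 1) projected back to the CNN feature
  width, summed with a fully-connected shortcut branch, then the retained
  head. Retaining and extending the pretrained head (the sequence block
  inserts before it) is an interpretation; the alternative — discarding a
  temporary pretraining head — is noted as equally consistent with the
  protocol description.

All layers and their backward passes are implemented in vectorised base R
(im2col convolutions, standard batch-norm and BPTT recursions) and are
verified against finite-difference gradients in the test suite.

## Two-stage training

1. **Pretraining** (default 100 epochs, batch 32 pairs, Adam, learning rate
   $10^{-3}$, weight decay $10^{-3}$): each step draws a balanced pair
   batch, computes both latents, the contrastive term, the reconstruction
   distance (AE), and classifies every epoch in the batch through the CNN
   block; all parameters update jointly.
2. **Finetuning** (default 200 epochs, batch 16 sequences of 25 epochs):
   CNN features of consecutive epochs pass through the sequence residual
   block. Pretrained blocks continue at learning rate $10^{-6}$, the
   sequence block at $10^{-3}$. The contrastive and reconstruction terms
   remain in the loss; their pairs are drawn from the epochs inside the
   current batch, which avoids a second data stream while keeping the
   Siamese term active.

Evaluation uses one encoder branch (sharing makes the choice immaterial)
and subject-wise $k$-fold cross-validation: subjects are shuffled under the
seed and dealt round-robin into $k$ test groups. Subject-wise rather than
epoch-wise splitting is essential — epochs within a subject are strongly
correlated, and $k = 20$ folds for 20 subjects (leave-one-subject-out)
matches the reference protocol. Fold confusion matrices are **summed**
before metrics are computed, not averaged as per-fold metrics.

The margin default $m = 7400$ presumes unnormalized microvolt-scale inputs
and latent spaces of the full-size networks; it is a configuration value,
not a constant. The tiny profile sets $m = 20$, commensurate with the
latent distances of its 16-dimensional encoder on the synthetic signals.

## Metrics

From the summed confusion matrix (rows = human scores, columns = model):
per-class precision, recall and F1; overall accuracy (trace over total);
macro-F1 as the unweighted mean of the five *full-precision* F1 values; and
Cohen's kappa $(ACC - P_e)/(1 - P_e)$ with $P_e$ the marginal chance
agreement. Recomputing the published pooled matrices shows the
full-precision macro-F1 definition reproduces the printed overall rows to
one decimal for the autoencoder variant, while the CNN-variant summary row
differs from its own pooled matrix by ≤ 0.1 — the pooled-matrix definition
is adopted and the discrepancy tolerated in the golden tests. A class
absent from both margins yields `NA`, never a silent zero, since small
synthetic runs can miss classes. Half-up rounding to one decimal is applied
only at presentation.

## The synthetic generator

Real scored PSG cannot ship with a package, so `generate_cohort()` produces
stage-conditioned surrogate EEG: each stage has a spectral profile
(wake alpha-dominant; N1 theta-dominant at low amplitude; N2 theta/delta
with 12–14 Hz spindle bursts under Hann envelopes, ~3 per epoch; N3
delta-dominant at high amplitude; REM mixed theta/beta), realized as
random-phase band-limited sinusoids plus white noise. Stage sequences come
from a first-order Markov chain with strong self-transitions (diagonal
0.85) and plausible off-diagonal structure, giving realistic stage runs for
25-epoch training sequences. Each subject receives an independent derived
seed and an amplitude factor drawn log-uniformly in $[0.8, 1.25]$, creating
the cross-subject variation that subject-wise folds are meant to exercise.

What this emulates: stage-dependent band power, spindle activity,
plausible transition statistics, inter-subject gain variation. What it does
not: 1/f background spectra, artifacts (movement, electrode pops), age and
pathology effects, within-night nonstationarity, or genuine class
imbalance. Tests passing on this generator therefore demonstrate that the
pipeline can extract and use stage-discriminative structure end-to-end —
not that it attains any particular accuracy on recorded polysomnography.

## Problem sizes and numerical choices

The test suite and the acceptance script run a deliberately small
configuration chosen as a desk-scale working point: a 4-subject cohort of
200 epochs each (800 epochs, ~6.7 h of signal per subject at 100 Hz),
2-fold subject-wise cross-validation, 5 pretraining + 5 finetuning epochs,
batches of 8 pairs / 2 sequences, latent dimension 16, filter counts one
eighth of the full model, bi-LSTM hidden size 32. Under these conditions
held-out accuracy lands well above the 20% five-class chance level while a
full run stays in the minutes range on one CPU core.

Other numerical conventions: He initialization for convolutions; batch-norm
$\epsilon = 10^{-5}$, running-statistics momentum 0.1; Adam
$(\beta_1, \beta_2) = (0.9, 0.999)$ with L2 weight decay added to the
gradient; dropout and pair sampling consume a single seeded RNG stream so a
single-threaded run is bitwise reproducible; a NaN/Inf loss aborts with a
diagnostic rather than training on. Pair sampling draws an exact
same/different split (default 50/50 — the reference protocol does not state
a ratio, and balanced pairs are the standard contrastive regime), never
pairs an epoch with itself (zero distance carries no gradient), and picks
different-stage pairs uniformly over *stage pairs* so the majority class
does not dominate the negatives. Training sequences are non-overlapping
and never span subjects; at prediction time a trailing partial window is
covered by re-running the subject's last `seq_len` epochs and keeping only
the tail predictions.

## Limitations

* The published full-scale accuracies require the real SleepEDF/MASS
  recordings and GPU-scale training of the full-width networks; this
  package validates the method's computational core (losses, metrics,
  architecture contracts, training dynamics) at desk scale instead.
* The exact kernel/stride/filter table of the original figures is not
  recoverable from text; the DeepSleepNet-derived geometry used here is a
  declared, config-overridable substitute.
* Wake trimming assumes a single sleep bout bounded by wake; split-night
  recordings would need manual segmentation.
* EDF support covers the common 16-bit continuous-signal layout only.
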