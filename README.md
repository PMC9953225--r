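# sleepsiam

Automatic sleep staging from single-channel EEG with Siamese encoders and
distance-metric losses.

Clinical sleep scoring labels every 30-second epoch of an overnight EEG as
one of five stages — wake (W), the non-REM depth grades N1/N2/N3, or REM.
`sleepsiam` implements a staging method whose core idea is to learn, with a
*Siamese* network (two applications of one shared-parameter encoder), a
latent space in which epochs from the same stage sit close together and
epochs from different stages are separated by a margin. The latent feature
of each epoch is concatenated with the raw signal and classified by a
two-branch CNN plus a bidirectional-LSTM sequence residual block. The
package is aimed at researchers studying representation learning for
biosignal classification who want a fully inspectable, CPU-scale
implementation of the method — every layer, gradient and loss is plain R.

## The model

For an epoch pair $(x_1, x_2)$ and shared encoder $G_W$, the latent
distance is $D_W = \lVert G_W(x_1) - G_W(x_2) \rVert_2$ and the
contrastive loss of a batch of $P$ pairs is the sum of

$$
\ell = \begin{cases}
\tfrac12 D_W^2 & \text{same stage}, \\
\tfrac12 \max(0,\, m - D_W)^2 & \text{different stage},
\end{cases}
$$

with margin $m$ (7400 in the full-scale configuration). Classification
adds a multi-class cross-entropy, and the autoencoder variant further adds
a reconstruction distance
$D(u,v) = \lVert u - v \rVert_2 + \widetilde{\max W_2}(u,v)$, where
$\widetilde{\max W_2}$ is the max-sliced Wasserstein-2 distance — the
largest 1-D optimal-transport distance between the two batches obtainable
by projecting both onto one unit direction. Training is two-stage:
pretraining of the Siamese encoder + CNN block on epoch pairs, then
finetuning with the sequence residual block at per-block learning rates
($10^{-6}$ for pretrained blocks, $10^{-3}$ for the sequence block).
Evaluation is subject-wise k-fold cross-validation with fold confusion
matrices summed before computing per-class precision/recall/F1, accuracy,
macro-F1 and Cohen's kappa.

A stage-conditioned synthetic EEG generator (delta-dominant N3,
spindle-burst N2, alpha-dominant wake, Markov stage transitions,
per-subject gain variation) makes the whole pipeline runnable and testable
with no data download. See `vignettes/siamese-sleep-staging.Rmd` for the
full account of the model, its assumptions and the design choices.

## Worked example

Score a published confusion matrix (shipped as a CSV fixture) through the
evaluation module:

```r
library(sleepsiam)
cm <- read_confusion_csv(system.file("extdata",
        "confusion_siamese_ae_mass.csv", package = "sleepsiam"))
metrics_report(cm)
#> per-class metrics (%):
#>  stage   PR   RE   F1
#>      W 87.1 90.8 88.9
#>     N1 64.5 51.0 56.9
#>     N2 91.1 91.5 91.3
#>     N3 88.2 81.9 85.0
#>    REM 84.0 93.1 88.3
#>
#> overall: ACC 87.2%  MF1 82.1%  kappa 0.81
```

`ACC` is the fraction of epochs scored correctly, `MF1` the unweighted
mean of the five per-class F1 scores, and `kappa` the chance-corrected
agreement between model and human scorer.

Train a small model end-to-end on synthetic EEG:

```r
cohort <- generate_cohort(n_subjects = 2, n_epochs = 75, fs = 100, seed = 42)
cohort
#> <epoch_set> 150 epochs, 2 subject(s), fs = 100 Hz
#>   stages: W=28 N1=29 N2=25 N3=25 REM=43

cfg <- train_config("tiny", epochs_pretrain = 3, epochs_finetune = 3)
fit <- fit_sleep_stager(cohort, variant = "ae", config = cfg)
fit
#> Siamese AE sleep stager (fs 100 Hz, latent 16)
#> trained on 150 epochs from 2 subject(s); 3 + 3 training epochs
#> final training loss 2000

predict(fit, cohort)          # stage codes, one per epoch
summary(fit)                  # per-epoch loss breakdown
```

The subject-wise cross-validated protocol is `cv_sleep_stager(cohort,
"ae", cfg)`; `summary()` of its result prints the summed confusion matrix
and all metrics. A command-line front end with `simulate / prepare /
pretrain / finetune / evaluate / metrics-from-matrix` subcommands is in
`inst/cli/sleepsiam.R`.

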