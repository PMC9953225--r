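# Shared fixtures and independent oracles for the test suite.

# Periodogram band-power fraction oracle (FFT-based, independent of the
# generator's construction).
band_power_fraction <- function(x, fs, lo, hi) {
  n <- length(x)
  p <- Mod(stats::fft(x - mean(x)))^2
  f <- (seq_len(n) - 1) * fs / n
  keep <- f <= fs / 2
  sum(p[keep & f >= lo & f <= hi]) / sum(p[keep])
}

# Dummy epoch_set with flat signals (fast; for label-logic tests where the
# waveform content is irrelevant).
flat_epoch_set <- function(stages, subject_id = "s1", fs = 100) {
  n <- length(stages)
  epoch_set(matrix(0, n, fs * 30), stages, subject_id,
            seq_len(n) - 1L, fs)
}

# Published confusion tables installed with the package.
table_csv <- function(name) {
  system.file("extdata", name, package = "sleepsiam", mustWork = TRUE)
}

published_tables <- function() {
  list(
    cnn_sleepedf = list(
      csv = "confusion_siamese_cnn_sleepedf.csv",
      per_class = data.frame(
        stage = c("W", "N1", "N2", "N3", "REM"),
        PR = c(87.5, 55.3, 87.0, 85.8, 82.8),
        RE = c(89.6, 33.1, 88.4, 86.8, 88.8),
        F1 = c(88.5, 41.4, 87.7, 86.3, 85.7)),
      overall = c(ACC = 84.9, MF1 = 78.0, kappa = 0.79)),
    ae_sleepedf = list(
      csv = "confusion_siamese_ae_sleepedf.csv",
      per_class = data.frame(
        stage = c("W", "N1", "N2", "N3", "REM"),
        PR = c(85.8, 55.6, 87.2, 86.5, 85.2),
        RE = c(91.4, 33.1, 88.7, 88.0, 87.5),
        F1 = c(88.5, 41.5, 87.9, 87.2, 86.4)),
      overall = c(ACC = 85.2, MF1 = 78.3, kappa = 0.79)),
    ae_mass = list(
      csv = "confusion_siamese_ae_mass.csv",
      per_class = data.frame(
        stage = c("W", "N1", "N2", "N3", "REM"),
        PR = c(87.1, 64.5, 91.1, 88.2, 84.0),
        RE = c(90.8, 50.9, 91.5, 81.9, 93.1),
        F1 = c(88.9, 56.9, 91.3, 85.0, 88.3)),
      overall = c(ACC = 87.2, MF1 = 82.1, kappa = 0.81)))
}

# Scratch environment for sharing expensive results across test blocks.
.acc_env <- new.env(parent = emptyenv())

# A small trained pipeline shared by structural tests (built once per run).
tiny_trained <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cohort <- generate_cohort(2, 50, fs = 100, seed = 401)
      cfg <- train_config("tiny", epochs_pretrain = 1, epochs_finetune = 1,
                          rng_seed = 7L)
      model <- siamese_model("ae", fs = 100, latent_dim = cfg$latent_dim,
                             filters = cfg$enc_filters, seed = 7L)
      staging <- staging_model(fs = 100, latent_dim = cfg$latent_dim,
                               filters = cfg$cnn_filters,
                               hidden = cfg$hidden, seed = 8L)
      pt <- pretrain(cohort, model, staging, cfg)
      ft <- finetune(cohort, pt$model, pt$staging, pt$state, cfg)
      cache <<- list(cohort = cohort, cfg = cfg, pre = pt, fin = ft)
    }
    cache
  }
})
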