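# Two-stage training: joint Siamese + CNN-block pretraining on epoch pairs,
# then finetuning with the sequence residual block at per-block learning
# rates (1e-6 for pretrained blocks, 1e-3 for the sequence block), plus
# subject-wise k-fold orchestration.

#' Training configuration
#'
#' All hyperparameters of the two-stage protocol. The `"paper"` profile
#' carries the full-scale values (margin 7400, 100 pretraining + 200
#' finetuning epochs, batches 32/16, 20 folds); the `"tiny"` profile is a
#' desk-scale configuration for synthetic cohorts (reduced epochs, batches,
#' network widths and margin, 2 folds) used throughout the test suite.
#'
#' @param profile `"paper"` or `"tiny"`.
#' @param ... named overrides of any field.
#' @return An object of class `"train_config"`.
#' @export
#' @examples
#' train_config("tiny", epochs_pretrain = 3)
train_config <- function(profile = c("paper", "tiny"), ...) {
  profile <- match.arg(profile)
  cfg <- list(
    profile = profile,
    margin_m = 7400, lr_pretrain = 1e-3, weight_decay = 1e-3,
    lr_finetune_pretrained = 1e-6, lr_finetune_sequence = 1e-3,
    epochs_pretrain = 100L, epochs_finetune = 200L,
    batch_pretrain = 32L, batch_finetune = 16L,
    seq_len = 25L, n_folds = 20L, dropout_p = 0.5, rng_seed = 1L,
    fs = 100, latent_dim = 128L, enc_filters = c(32L, 64L, 64L),
    cnn_filters = c(64L, 128L), hidden = 512L,
    msw_directions = 64L, msw_refine = 50L)
  if (profile == "tiny") {
    cfg[c("margin_m", "epochs_pretrain", "epochs_finetune",
          "batch_pretrain", "batch_finetune", "n_folds", "latent_dim",
          "enc_filters", "cnn_filters", "hidden",
          "msw_directions", "msw_refine")] <-
      list(20, 5L, 5L, 8L, 2L, 2L, 16L, c(4L, 8L, 8L), c(8L, 16L), 32L,
           8L, 5L)
  }
  over <- list(...)
  bad <- setdiff(names(over), names(cfg))
  if (length(bad)) stop("unknown train_config field(s): ",
                        paste(bad, collapse = ", "))
  cfg[names(over)] <- over
  stopifnot(cfg$margin_m > 0, cfg$lr_pretrain > 0,
            cfg$lr_finetune_pretrained > 0, cfg$lr_finetune_sequence > 0,
            cfg$seq_len >= 1)
  structure(cfg, class = "train_config")
}

#' @export
print.train_config <- function(x, ...) {
  cat(sprintf("<train_config> profile %s: m=%g, lr=%g/%g|%g, epochs=%d+%d, batches=%d/%d, seq_len=%d, k=%d\n",
              x$profile, x$margin_m, x$lr_pretrain, x$lr_finetune_pretrained,
              x$lr_finetune_sequence, x$epochs_pretrain, x$epochs_finetune,
              x$batch_pretrain, x$batch_finetune, x$seq_len, x$n_folds))
  invisible(x)
}

# Small polynomial rolling hash of a deparse()d object, for checkpoint
# compatibility checks (not cryptographic).
config_hash <- function(x) {
  s <- paste(deparse(x), collapse = "")
  h <- 5381
  for (b in utf8ToInt(s)) h <- (h * 127 + b) %% 2147483629
  sprintf("%08x", h)
}

#' Subject-wise k-fold splits
#'
#' Subjects are shuffled deterministically under the seed and dealt
#' round-robin into `k` test groups, so every subject is tested exactly
#' once. With `k == length(subjects)` this is leave-one-subject-out.
#'
#' @param subjects character vector of subject ids.
#' @param k number of folds (2 <= k <= number of subjects).
#' @param seed RNG seed for the shuffle.
#' @return List of fold splits, each a list with `fold_index`,
#'   `train_subjects`, `test_subjects`.
#' @export
make_folds <- function(subjects, k, seed = 1L) {
  subjects <- unique(as.character(subjects))
  if (k > length(subjects)) stop("k exceeds the number of subjects")
  if (k < 2L) stop("need at least 2 folds")
  shuffled <- with_seed(seed, sample(subjects))
  groups <- split(shuffled, rep_len(seq_len(k), length(shuffled)))
  lapply(seq_len(k), function(i) {
    list(fold_index = i, train_subjects = sort(setdiff(subjects, groups[[i]])),
         test_subjects = sort(groups[[i]]))
  })
}

# ---- loss gradients -------------------------------------------------------

# Contrastive loss (sum over pairs) and its gradient wrt the two latent
# matrices A, B (one pair per row).
contrastive_grad <- function(A, B, same, m) {
  diff <- A - B
  d <- sqrt(rowSums(diff^2))
  loss <- sum(ifelse(same, 0.5 * d^2, 0.5 * pmax(0, m - d)^2))
  coef <- ifelse(same, 1, ifelse(d > 0 & d < m, -(m - d) / d, 0))
  dA <- diff * coef
  list(loss = loss, dA = dA, dB = -dA)
}

# Combined reconstruction distance D(X, R) and gradient wrt R.
combined_distance_grad <- function(X, R, n_directions, n_refine, seed) {
  n <- nrow(X)
  rn <- sqrt(rowSums((X - R)^2))
  euc <- mean(rn)
  dR <- (R - X) / pmax(rn, 1e-12) / n
  if (n >= 2L) {
    msw <- max_sliced_w2(X, R, n_directions, n_refine, seed)
    w <- attr(msw, "direction")
    val <- as.numeric(msw)
    if (!is.null(w) && val > 1e-12) {
      pu <- drop(X %*% w); pv <- drop(R %*% w)
      ou <- order(pu); ov <- order(pv)
      diffs <- pu[ou] - pv[ov]
      # d sqrt(mean diffs^2) / d pv[ov[t]] = -diffs[t] / (n * val)
      dproj <- numeric(n)
      dproj[ov] <- -diffs / (n * val)
      dR <- dR + outer(dproj, w)
    }
  } else {
    val <- wasserstein2_1d(X[1L, ], R[1L, ])
    if (val > 1e-12) {
      ou <- order(X[1L, ]); ov <- order(R[1L, ])
      diffs <- X[1L, ou] - R[1L, ov]
      dv <- numeric(ncol(X))
      dv[ov] <- -diffs / (length(diffs) * val)
      dR <- dR + matrix(dv, 1L)
    }
    msw <- val
  }
  list(value = euc + as.numeric(msw), dR = dR)
}

# ---- pretraining ----------------------------------------------------------

new_train_state <- function(config) {
  structure(list(stage = "init", epoch_counter = 0L,
                 loss_history = list(), subjects_seen = character(0),
                 opt = NULL, config = config),
            class = "train_state")
}

#' @export
print.train_state <- function(x, ...) {
  cat(sprintf("<train_state> stage %s, %d training epochs recorded\n",
              x$stage, length(x$loss_history)))
  invisible(x)
}

# One joint forward/backward/update on a batch of pairs. Returns updated
# models, optimizer state and the loss breakdown.
pretrain_step <- function(es, pair_idx, model, staging, config, opt, t_step,
                          msw_seed) {
  rows <- c(pair_idx$first, pair_idx$second)
  P <- nrow(pair_idx)
  X <- es$x[rows, , drop = FALSE]
  labels <- es$stage[rows]

  enc <- encoder_fwd(model, X, train = TRUE)
  if (model$variant == "ae") {
    model$params$encoder <- enc$params
  } else {
    model$params[c("branch1", "branch2", "proj")] <-
      enc$params[c("branch1", "branch2", "proj")]
  }
  lat <- enc$latent

  cg <- contrastive_grad(lat[seq_len(P), , drop = FALSE],
                         lat[P + seq_len(P), , drop = FALSE],
                         pair_idx$same_stage, config$margin_m)
  dLat <- rbind(cg$dA, cg$dB)

  recon_val <- 0
  dec_grads <- NULL
  if (model$variant == "ae") {
    dec <- decoder_fwd(model, lat, train = TRUE)
    model$params$decoder <- dec$params
    rg <- combined_distance_grad(X, dec$recon, config$msw_directions,
                                 config$msw_refine, msw_seed)
    recon_val <- rg$value
    db <- decoder_bwd(model, dec$caches, rg$dR)
    dec_grads <- db$grads$decoder
    dLat <- dLat + db$dLatent
  }

  aug <- cbind(X, lat)
  cb <- cnn_block_fwd(staging, aug, train = TRUE)
  staging$params[c("branch1", "branch2")] <-
    cb$params[c("branch1", "branch2")]
  hd <- head_fwd(staging, cb$feat)
  sc <- softmax_ce(hd$out, stage_index(labels) + 1L)
  ghead <- linear_bwd(hd$cache, sc$dlogits)
  gcnn <- cnn_block_bwd(staging, cb$caches, ghead$dX)
  dAug <- gcnn$dX
  dim(dAug) <- dim(aug)
  dLat <- dLat + dAug[, model$L + seq_len(model$latent_dim), drop = FALSE]

  genc <- encoder_bwd(model, enc$caches, dLat)

  bl <- loss_breakdown(sc$loss, cg$loss, recon_val)
  if (!is.finite(bl$total)) {
    stop("NaN/Inf loss at pretraining step ", t_step,
         " (CE=", sc$loss, ", CT=", cg$loss, ", recon=", recon_val,
         "); consider lowering lr_pretrain or the contrastive margin")
  }

  grads <- list(siamese = genc$grads,
                staging = list(branch1 = gcnn$grads$branch1,
                               branch2 = gcnn$grads$branch2,
                               head = list(list(W = ghead$dW, b = ghead$db))))
  if (!is.null(dec_grads)) grads$siamese$decoder <- dec_grads
  params <- list(siamese = model$params,
                 staging = staging$params[c("branch1", "branch2", "head")])
  up <- adam_step(params, grads, opt, config$lr_pretrain, t_step,
                  config$weight_decay)
  model$params <- up$p$siamese
  staging$params[c("branch1", "branch2", "head")] <- up$p$staging
  list(model = model, staging = staging, opt = up$s, loss = bl)
}

#' Pretrain the Siamese network jointly with the CNN staging block
#'
#' Per step a batch of epoch pairs is drawn from the training set; the
#' shared encoder produces both latents, the contrastive term compares
#' them, the AE variant also reconstructs the batch and measures the
#' combined Euclidean + max-sliced-W2 distance, and every epoch in the
#' batch is classified through its augmented (epoch + latent) input by the
#' CNN block and head for the cross-entropy term. All parameters update
#' with Adam at `lr_pretrain`.
#'
#' @param es training `epoch_set` (training subjects only).
#' @param model a `siamese_model`.
#' @param staging a `staging_model` with matching `latent_dim`.
#' @param config a `train_config`.
#' @return A list with updated `model`, `staging` and a `train_state` whose
#'   `loss_history` holds one averaged `loss_breakdown` per training epoch.
#' @export
pretrain <- function(es, model, staging, config) {
  stopifnot(inherits(es, "epoch_set"), inherits(model, "siamese_model"),
            inherits(staging, "staging_model"),
            inherits(config, "train_config"))
  state <- new_train_state(config)
  state$stage <- "pretrain"
  state$subjects_seen <- unique(es$subject_id)
  opt <- adam_init(list(siamese = model$params,
                        staging = staging$params[c("branch1", "branch2",
                                                   "head")]))
  n <- n_epochs(es)
  steps_per_epoch <- max(1L, n %/% (2L * config$batch_pretrain))
  t_step <- 0L
  with_seed(config$rng_seed, {
    for (ep in seq_len(config$epochs_pretrain)) {
      comps <- matrix(0, steps_per_epoch, 3L)
      for (s in seq_len(steps_per_epoch)) {
        t_step <- t_step + 1L
        pair_seed <- sample.int(.Machine$integer.max - 1L, 1L)
        msw_seed <- sample.int(.Machine$integer.max - 1L, 1L)
        pairs <- sample_pairs(es, pair_sampler_config(config$batch_pretrain,
                                                      0.5, pair_seed))
        r <- pretrain_step(es, pairs, model, staging, config, opt, t_step,
                           msw_seed)
        model <- r$model; staging <- r$staging; opt <- r$opt
        comps[s, ] <- c(r$loss$cross_entropy, r$loss$contrastive,
                        r$loss$reconstruction)
      }
      m <- colMeans(comps)
      state$loss_history[[ep]] <- loss_breakdown(m[1], m[2], m[3])
      state$epoch_counter <- ep
    }
  })
  state$opt <- opt
  list(model = model, staging = staging, state = state)
}

# ---- finetuning -----------------------------------------------------------

finetune_step <- function(es, seq_rows, model, staging, config, opt_pre,
                          opt_seq, t_step, pair_seed, msw_seed) {
  Bq <- length(seq_rows)
  Tn <- config$seq_len
  rows <- unlist(seq_rows)
  X <- es$x[rows, , drop = FALSE]
  labels <- es$stage[rows]
  nb <- length(rows)

  enc <- encoder_fwd(model, X, train = TRUE)
  if (model$variant == "ae") {
    model$params$encoder <- enc$params
  } else {
    model$params[c("branch1", "branch2", "proj")] <-
      enc$params[c("branch1", "branch2", "proj")]
  }
  lat <- enc$latent

  # contrastive pairs from the epochs inside this batch
  sub <- epoch_subset(es, rows)
  n_pairs <- min(config$batch_pretrain, nb %/% 2L)
  pr <- tryCatch(
    sample_pairs(sub, pair_sampler_config(n_pairs, 0.5, pair_seed)),
    error = function(e) NULL)  # e.g. single-stage batch
  if (!is.null(pr)) {
    cg <- contrastive_grad(lat[pr$first, , drop = FALSE],
                           lat[pr$second, , drop = FALSE],
                           pr$same_stage, config$margin_m)
    ct_val <- cg$loss
    dLat <- matrix(0, nb, ncol(lat))
    for (i in seq_len(nrow(pr))) {
      dLat[pr$first[i], ] <- dLat[pr$first[i], ] + cg$dA[i, ]
      dLat[pr$second[i], ] <- dLat[pr$second[i], ] + cg$dB[i, ]
    }
  } else {
    ct_val <- 0
    dLat <- matrix(0, nb, ncol(lat))
  }

  recon_val <- 0
  dec_grads <- NULL
  if (model$variant == "ae") {
    dec <- decoder_fwd(model, lat, train = TRUE)
    model$params$decoder <- dec$params
    rg <- combined_distance_grad(X, dec$recon, config$msw_directions,
                                 config$msw_refine, msw_seed)
    recon_val <- rg$value
    db <- decoder_bwd(model, dec$caches, rg$dR)
    dec_grads <- db$grads$decoder
    dLat <- dLat + db$dLatent
  }

  aug <- cbind(X, lat)
  cb <- cnn_block_fwd(staging, aug, train = TRUE)
  staging$params[c("branch1", "branch2")] <-
    cb$params[c("branch1", "branch2")]
  F3 <- cb$feat
  dim(F3) <- c(Tn, Bq, staging$feat_dim)   # rows are seq-major
  F3 <- aperm(F3, c(2, 1, 3))
  sq <- seq_block_fwd(staging, F3, train = TRUE)
  feat <- aperm(sq$out, c(2, 1, 3))
  dim(feat) <- c(nb, staging$feat_dim)
  hd <- head_fwd(staging, feat)
  sc <- softmax_ce(hd$out, stage_index(labels) + 1L)

  ghead <- linear_bwd(hd$cache, sc$dlogits)
  dSeqOut <- ghead$dX
  dim(dSeqOut) <- c(Tn, Bq, staging$feat_dim)
  dSeqOut <- aperm(dSeqOut, c(2, 1, 3))
  gseq <- seq_block_bwd(staging, sq$caches, dSeqOut)
  dFeat <- aperm(gseq$dFeat3, c(2, 1, 3))
  dim(dFeat) <- c(nb, staging$feat_dim)
  gcnn <- cnn_block_bwd(staging, cb$caches, dFeat)
  dAug <- gcnn$dX
  dim(dAug) <- dim(aug)
  dLat <- dLat + dAug[, model$L + seq_len(model$latent_dim), drop = FALSE]
  genc <- encoder_bwd(model, enc$caches, dLat)

  bl <- loss_breakdown(sc$loss, ct_val, recon_val)
  if (!is.finite(bl$total)) {
    stop("NaN/Inf loss at finetuning step ", t_step,
         "; consider lowering the sequence-block learning rate")
  }

  pre_grads <- list(siamese = genc$grads,
                    staging = list(branch1 = gcnn$grads$branch1,
                                   branch2 = gcnn$grads$branch2,
                                   head = list(list(W = ghead$dW,
                                                    b = ghead$db))))
  if (!is.null(dec_grads)) pre_grads$siamese$decoder <- dec_grads
  pre_params <- list(siamese = model$params,
                     staging = staging$params[c("branch1", "branch2",
                                                "head")])
  up_pre <- adam_step(pre_params, pre_grads, opt_pre,
                      config$lr_finetune_pretrained, t_step,
                      config$weight_decay)
  model$params <- up_pre$p$siamese
  staging$params[c("branch1", "branch2", "head")] <- up_pre$p$staging

  up_seq <- adam_step(list(seq = staging$params$seq),
                      list(seq = gseq$grads), opt_seq,
                      config$lr_finetune_sequence, t_step,
                      config$weight_decay)
  staging$params$seq <- up_seq$p$seq

  list(model = model, staging = staging, opt_pre = up_pre$s,
       opt_seq = up_seq$s, loss = bl)
}

#' Finetune with the sequence residual block
#'
#' Continues from pretrained parameters: batches of `batch_finetune`
#' sequences of `seq_len` consecutive epochs pass through encoder,
#' concatenation, CNN block and the sequence residual block; the composite
#' loss keeps the contrastive term (pairs drawn from the batch's own
#' epochs) and, for the AE variant, the reconstruction distance. Pretrained
#' blocks update at `lr_finetune_pretrained` (1e-6), the sequence block at
#' `lr_finetune_sequence` (1e-3).
#'
#' @param es training `epoch_set`.
#' @param model pretrained `siamese_model`.
#' @param staging pretrained `staging_model`.
#' @param state the `train_state` returned by [pretrain()].
#' @param config a `train_config`.
#' @return A list with updated `model`, `staging`, `state`.
#' @export
finetune <- function(es, model, staging, state, config) {
  stopifnot(inherits(state, "train_state"))
  if (!identical(state$stage, "pretrain")) {
    stop("finetune requires the train_state produced by pretrain()")
  }
  seqs <- make_sequences(es, config$seq_len)
  if (length(seqs) == 0L) {
    stop("no complete sequences of length ", config$seq_len,
         " available for finetuning")
  }
  state$stage <- "finetune"
  state$subjects_seen <- union(state$subjects_seen, unique(es$subject_id))
  opt_pre <- adam_init(list(siamese = model$params,
                            staging = staging$params[c("branch1", "branch2",
                                                       "head")]))
  opt_seq <- adam_init(list(seq = staging$params$seq))
  t_step <- 0L
  hist_offset <- length(state$loss_history)
  with_seed(config$rng_seed + 1L, {
    for (ep in seq_len(config$epochs_finetune)) {
      ord <- sample(length(seqs))
      batches <- split(ord, ceiling(seq_along(ord) / config$batch_finetune))
      comps <- matrix(0, length(batches), 3L)
      for (bi in seq_along(batches)) {
        t_step <- t_step + 1L
        pair_seed <- sample.int(.Machine$integer.max - 1L, 1L)
        msw_seed <- sample.int(.Machine$integer.max - 1L, 1L)
        r <- finetune_step(es, seqs[batches[[bi]]], model, staging, config,
                           opt_pre, opt_seq, t_step, pair_seed, msw_seed)
        model <- r$model; staging <- r$staging
        opt_pre <- r$opt_pre; opt_seq <- r$opt_seq
        comps[bi, ] <- c(r$loss$cross_entropy, r$loss$contrastive,
                         r$loss$reconstruction)
      }
      m <- colMeans(comps)
      state$loss_history[[hist_offset + ep]] <- loss_breakdown(m[1], m[2], m[3])
      state$epoch_counter <- ep
    }
  })
  state$opt <- list(pre = opt_pre, seq = opt_seq)
  list(model = model, staging = staging, state = state)
}

# ---- prediction -----------------------------------------------------------

#' Predict stages for one subject's epochs
#'
#' Encodes each epoch through the (single) encoder branch, augments it with
#' its latent, and classifies non-overlapping `seq_len` windows through the
#' finetuned model. A trailing partial window is covered by re-running the
#' subject's last `seq_len` epochs and keeping only the tail predictions;
#' subjects shorter than `seq_len` are front-padded by repeating their
#' first epoch.
#'
#' @param model a `siamese_model`.
#' @param staging a finetuned `staging_model`.
#' @param es `epoch_set` of one subject (ordered by `epoch_index`).
#' @param seq_len sequence length used at finetuning.
#' @return Character vector of predicted stage codes, one per epoch, in row
#'   order of `es`.
#' @export
predict_stages <- function(model, staging, es, seq_len = 25L) {
  n <- n_epochs(es)
  ord <- order(es$epoch_index)
  X <- es$x[ord, , drop = FALSE]
  lat <- encoder_fwd(model, X, train = FALSE)$latent
  aug <- cbind(X, lat)
  pred <- character(n)
  predict_window <- function(rows) {
    probs <- forward_staging(staging, aug[rows, , drop = FALSE],
                             mode = "finetune", seq_len = seq_len)
    stage_levels()[max.col(probs, ties.method = "first")]
  }
  if (n < seq_len) {
    padded <- rbind(matrix(rep(aug[1L, ], seq_len - n), seq_len - n,
                           byrow = TRUE), aug)
    probs <- forward_staging(staging, padded, mode = "finetune",
                             seq_len = seq_len)
    pred <- stage_levels()[max.col(probs, ties.method = "first")][
      (seq_len - n + 1L):seq_len]
  } else {
    nw <- n %/% seq_len
    for (w in seq_len(nw)) {
      rows <- ((w - 1L) * seq_len + 1L):(w * seq_len)
      pred[rows] <- predict_window(rows)
    }
    rem <- n - nw * seq_len
    if (rem > 0L) {
      rows <- (n - seq_len + 1L):n
      tail_pred <- predict_window(rows)
      pred[(n - rem + 1L):n] <- tail_pred[(seq_len - rem + 1L):seq_len]
    }
  }
  out <- character(n)
  out[ord] <- pred
  out
}

# ---- cross-validation -----------------------------------------------------

#' Subject-wise k-fold cross-validation of the full protocol
#'
#' For each fold: fresh models are initialized, pretrained and finetuned on
#' the training subjects only, then the held-out subjects' epochs are
#' scored through one encoder branch and the staging model. Fold confusion
#' matrices are accumulated by summation.
#'
#' @param cohort pooled `epoch_set` with at least `config$n_folds` subjects.
#' @param config a `train_config`.
#' @param variant Siamese variant, `"ae"` or `"cnn"`.
#' @return An object of class `"cv_result"`: `predictions` (data.frame with
#'   subject, epoch_index, true, predicted, fold), `confusion` (summed
#'   5x5 `confusion_matrix`), `fold_confusions`, `folds`, `states`.
#' @export
run_cross_validation <- function(cohort, config = train_config("tiny"),
                                 variant = c("ae", "cnn")) {
  variant <- match.arg(variant)
  stopifnot(inherits(cohort, "epoch_set"))
  subjects <- unique(cohort$subject_id)
  if (length(subjects) < config$n_folds) {
    stop("cohort has fewer subjects than folds")
  }
  folds <- make_folds(subjects, config$n_folds, config$rng_seed)
  preds <- list()
  fold_cms <- list()
  states <- list()
  for (f in folds) {
    tr <- epoch_subset(cohort, which(cohort$subject_id %in% f$train_subjects))
    fit <- fit_models(tr, variant, config, seed_offset = f$fold_index)
    fold_pred <- list()
    for (sid in f$test_subjects) {
      te <- epoch_subset(cohort, which(cohort$subject_id == sid))
      p <- predict_stages(fit$model, fit$staging, te, config$seq_len)
      fold_pred[[sid]] <- data.frame(subject = sid,
                                     epoch_index = te$epoch_index,
                                     true = te$stage, predicted = p,
                                     fold = f$fold_index,
                                     stringsAsFactors = FALSE)
    }
    fold_df <- do.call(rbind, fold_pred)
    preds[[f$fold_index]] <- fold_df
    fold_cms[[f$fold_index]] <- confusion_matrix(fold_df$true,
                                                 fold_df$predicted)
    states[[f$fold_index]] <- fit$state
  }
  all_pred <- do.call(rbind, preds)
  total <- Reduce(`+`, lapply(fold_cms, unclass))
  structure(list(predictions = all_pred,
                 confusion = structure(total, class = "confusion_matrix"),
                 fold_confusions = fold_cms, folds = folds,
                 states = states, config = config, variant = variant),
            class = "cv_result")
}

# Build + pretrain + finetune on a training set; internal shared by
# run_cross_validation() and fit_sleep_stager().
fit_models <- function(tr, variant, config, seed_offset = 0L) {
  model <- siamese_model(variant, fs = config$fs,
                         latent_dim = config$latent_dim,
                         filters = if (variant == "ae") config$enc_filters
                                   else config$cnn_filters,
                         dropout_p = config$dropout_p,
                         seed = config$rng_seed + 1000L * seed_offset)
  staging <- staging_model(fs = config$fs, latent_dim = config$latent_dim,
                           filters = config$cnn_filters,
                           hidden = config$hidden,
                           dropout_p = config$dropout_p,
                           seed = config$rng_seed + 1000L * seed_offset + 1L)
  pt <- pretrain(tr, model, staging, config)
  ft <- finetune(tr, pt$model, pt$staging, pt$state, config)
  ft
}

#' @export
print.cv_result <- function(x, ...) {
  om <- overall_metrics(x$confusion)
  cat(sprintf("<cv_result> %s variant, %d folds, %d scored epochs\n",
              toupper(x$variant), length(x$folds), sum(x$confusion)))
  cat(sprintf("  ACC %.1f%%, MF1 %.1f%%, kappa %.2f\n",
              om$ACC, om$MF1, om$kappa))
  invisible(x)
}

# ---- checkpoints ----------------------------------------------------------

#' Save a training checkpoint
#'
#' Stores both models, the train state and a hash of the architecture
#' configuration; [load_checkpoint()] refuses files whose architecture does
#' not match what the caller expects.
#'
#' @param path file path.
#' @param model a `siamese_model`.
#' @param staging a `staging_model`.
#' @param state a `train_state` (optional).
#' @return `path`, invisibly.
#' @export
save_checkpoint <- function(path, model, staging, state = NULL) {
  arch <- list(variant = model$variant, fs = model$fs,
               latent_dim = model$latent_dim, filters = model$filters,
               feat_dim = staging$feat_dim, hidden = staging$hidden)
  obj <- list(format = "sleepsiam-checkpoint", version = 1L,
              arch_hash = config_hash(arch), arch = arch,
              model = model, staging = staging, state = state)
  saveRDS(obj, path)
  invisible(path)
}

#' Load a training checkpoint
#'
#' @param path file path written by [save_checkpoint()].
#' @param expected_arch optional architecture list to validate against
#'   (same fields as stored); a hash mismatch is an error.
#' @return List with `model`, `staging`, `state`, `arch`.
#' @export
load_checkpoint <- function(path, expected_arch = NULL) {
  obj <- readRDS(path)
  if (!identical(obj$format, "sleepsiam-checkpoint")) {
    stop("not a sleepsiam checkpoint: ", path)
  }
  if (obj$version != 1L) stop("unsupported checkpoint version: ", obj$version)
  if (!is.null(expected_arch) &&
      !identical(config_hash(expected_arch), obj$arch_hash)) {
    stop("checkpoint architecture mismatch: refusing to load")
  }
  obj[c("model", "staging", "state", "arch")]
}
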