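#' Fit a Siamese sleep stager
#'
#' The package's top-level fitting function: builds the Siamese encoder and
#' staging model from `config`, runs the two-stage protocol (pretraining on
#' epoch pairs, finetuning with the sequence residual block) on the given
#' cohort, and returns a fitted object with the usual methods.
#'
#' @param cohort an `epoch_set` of training data (see [generate_cohort()]
#'   or [read_cohort()]).
#' @param variant Siamese encoder variant: `"ae"` (autoencoder, adds the
#'   reconstruction distance to the loss) or `"cnn"`.
#' @param config a [train_config()].
#' @return An object of class `"sleep_stager"` with components `model`
#'   (the `siamese_model`), `staging`, `state` (loss history), `config`,
#'   `variant`.
#' @seealso [cv_sleep_stager()] for the subject-wise k-fold protocol,
#'   [predict.sleep_stager()].
#' @export
#' @examples
#' \donttest{
#' cohort <- generate_cohort(2, 60, fs = 100, seed = 1)
#' cfg <- train_config("tiny", epochs_pretrain = 1, epochs_finetune = 1)
#' fit <- fit_sleep_stager(cohort, "cnn", cfg)
#' table(predict(fit, cohort), cohort$stage)
#' }
fit_sleep_stager <- function(cohort, variant = c("ae", "cnn"),
                             config = train_config("tiny")) {
  variant <- match.arg(variant)
  stopifnot(inherits(cohort, "epoch_set"), inherits(config, "train_config"))
  ft <- fit_models(cohort, variant, config)
  structure(list(model = ft$model, staging = ft$staging, state = ft$state,
                 config = config, variant = variant,
                 subjects = unique(cohort$subject_id),
                 n_train = n_epochs(cohort)),
            class = "sleep_stager")
}

#' @export
print.sleep_stager <- function(x, ...) {
  cat(sprintf("Siamese %s sleep stager (fs %g Hz, latent %d)\n",
              toupper(x$variant), x$config$fs, x$config$latent_dim))
  cat(sprintf("trained on %d epochs from %d subject(s); %d + %d training epochs\n",
              x$n_train, length(x$subjects), x$config$epochs_pretrain,
              x$config$epochs_finetune))
  lh <- x$state$loss_history
  cat(sprintf("final training loss %.4g\n", lh[[length(lh)]]$total))
  invisible(x)
}

#' @export
summary.sleep_stager <- function(object, ...) {
  lh <- object$state$loss_history
  df <- data.frame(
    epoch = seq_along(lh),
    stage = c(rep("pretrain", object$config$epochs_pretrain),
              rep("finetune", length(lh) - object$config$epochs_pretrain)),
    total = vapply(lh, function(l) l$total, numeric(1)),
    cross_entropy = vapply(lh, function(l) l$cross_entropy, numeric(1)),
    contrastive = vapply(lh, function(l) l$contrastive, numeric(1)),
    reconstruction = vapply(lh, function(l) l$reconstruction, numeric(1)))
  out <- list(loss = df, variant = object$variant, config = object$config,
              n_parameters = n_parameters(object$model$params) +
                n_parameters(object$staging$params))
  class(out) <- "summary.sleep_stager"
  out
}

#' @export
print.summary.sleep_stager <- function(x, ...) {
  cat(sprintf("Siamese %s stager, %d parameters\n", toupper(x$variant),
              x$n_parameters))
  cat("loss history (per training epoch):\n")
  print(x$loss, row.names = FALSE, digits = 4)
  invisible(x)
}

#' Predict sleep stages for new epochs
#'
#' Scores every epoch of `newdata` through one branch of the Siamese
#' encoder and the finetuned staging model, subject by subject.
#'
#' @param object a fitted `sleep_stager`.
#' @param newdata an `epoch_set`.
#' @param type `"stage"` for stage codes (default) or `"prob"` for the
#'   matrix of class probabilities.
#' @param ... unused.
#' @return Character vector of stage codes, or a numeric probability
#'   matrix with one row per epoch.
#' @export
predict.sleep_stager <- function(object, newdata,
                                 type = c("stage", "prob"), ...) {
  type <- match.arg(type)
  stopifnot(inherits(newdata, "epoch_set"))
  out_stage <- character(n_epochs(newdata))
  out_prob <- matrix(NA_real_, n_epochs(newdata), 5L,
                     dimnames = list(NULL, stage_levels()))
  for (sid in unique(newdata$subject_id)) {
    rows <- which(newdata$subject_id == sid)
    sub <- epoch_subset(newdata, rows)
    out_stage[rows] <- predict_stages(object$model, object$staging, sub,
                                      object$config$seq_len)
  }
  if (type == "stage") return(out_stage)
  # probability output: per-epoch forward in pretrain mode is order-free,
  # but stage predictions above come from the sequence model; report the
  # sequence-model probabilities window by window for consistency
  for (sid in unique(newdata$subject_id)) {
    rows <- which(newdata$subject_id == sid)
    sub <- epoch_subset(newdata, rows)
    lat <- encoder_fwd(object$model, sub$x, train = FALSE)$latent
    aug <- cbind(sub$x, lat)
    sl <- object$config$seq_len
    n <- length(rows)
    i <- 1L
    while (i <= n) {
      win <- if (i + sl - 1L <= n) i:(i + sl - 1L) else (max(1L, n - sl + 1L)):n
      if (length(win) < sl) {
        pad <- matrix(rep(aug[win[1L], ], sl - length(win)),
                      sl - length(win), byrow = TRUE)
        pr <- forward_staging(object$staging, rbind(pad, aug[win, ,
                                                             drop = FALSE]),
                              "finetune", sl)
        pr <- pr[(sl - length(win) + 1L):sl, , drop = FALSE]
      } else {
        pr <- forward_staging(object$staging, aug[win, , drop = FALSE],
                              "finetune", sl)
      }
      out_prob[rows[win], ] <- pr
      i <- i + sl
    }
  }
  out_prob
}

#' Plot training loss curves
#'
#' @param x a fitted `sleep_stager`.
#' @param ... further arguments to [graphics::matplot()].
#' @return `x`, invisibly.
#' @export
plot.sleep_stager <- function(x, ...) {
  s <- summary(x)$loss
  graphics::matplot(s$epoch, log10(1e-12 + cbind(s$total, s$cross_entropy,
                                                 s$contrastive,
                                                 s$reconstruction)),
                    type = "l", lty = 1, xlab = "training epoch",
                    ylab = "log10 loss", ...)
  graphics::abline(v = x$config$epochs_pretrain + 0.5, lty = 3)
  graphics::legend("topright",
                   c("total", "cross-entropy", "contrastive",
                     "reconstruction"),
                   col = 1:4, lty = 1, bty = "n")
  invisible(x)
}

#' Cross-validated Siamese sleep staging
#'
#' Formula-free front end to [run_cross_validation()]: subject-wise k-fold
#' evaluation of the full two-stage protocol, with confusion matrices
#' summed over folds.
#'
#' @inheritParams fit_sleep_stager
#' @return A `cv_result` (see [run_cross_validation()]).
#' @export
cv_sleep_stager <- function(cohort, variant = c("ae", "cnn"),
                            config = train_config("tiny")) {
  run_cross_validation(cohort, config, match.arg(variant))
}

#' @export
summary.cv_result <- function(object, ...) metrics_report(object$confusion)
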