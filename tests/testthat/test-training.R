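test_that("subject-wise folds partition subjects exactly once", {
  subj20 <- sprintf("p%02d", 1:20)
  loso <- make_folds(subj20, 20, seed = 1)
  expect_length(loso, 20)
  expect_true(all(vapply(loso, function(f) length(f$test_subjects),
                         integer(1)) == 1L))
  expect_setequal(unlist(lapply(loso, `[[`, "test_subjects")), subj20)

  f2 <- make_folds(c("a", "b", "c", "d"), 2, seed = 3)
  expect_length(f2, 2)
  expect_true(all(vapply(f2, function(f) length(f$test_subjects),
                         integer(1)) == 2L))
  for (f in f2) {
    expect_length(intersect(f$train_subjects, f$test_subjects), 0)
  }
  expect_identical(make_folds(subj20, 5, seed = 9),
                   make_folds(subj20, 5, seed = 9))
  expect_error(make_folds(c("a", "b"), 3), "exceeds")
})

test_that("pretraining reduces the composite loss and is seed-reproducible", {
  tt <- tiny_trained()
  cohort <- tt$cohort
  cfg <- train_config("tiny", epochs_pretrain = 2, epochs_finetune = 1,
                      rng_seed = 7L)
  model <- siamese_model("ae", fs = 100, latent_dim = cfg$latent_dim,
                         filters = cfg$enc_filters, seed = 7L)
  staging <- staging_model(fs = 100, latent_dim = cfg$latent_dim,
                           filters = cfg$cnn_filters, hidden = cfg$hidden,
                           seed = 8L)
  pt <- pretrain(cohort, model, staging, cfg)
  hist <- pt$state$loss_history
  expect_length(hist, 2)
  expect_lt(hist[[2]]$total, hist[[1]]$total)
  expect_true(all(vapply(hist, function(l) l$contrastive >= 0, logical(1))))
  pt2 <- pretrain(cohort, model, staging, cfg)
  expect_equal(vapply(pt2$state$loss_history, `[[`, numeric(1), "total"),
               vapply(hist, `[[`, numeric(1), "total"), tolerance = 1e-12)
})

test_that("weight sharing survives training steps", {
  tt <- tiny_trained()
  e <- epoch_at(tt$cohort, 3)
  l1 <- encode_epoch(tt$fin$model, e)
  l2 <- encode_epoch(tt$fin$model, e)
  expect_identical(l1, l2)
  # and the batch path uses the same single parameter set
  lat <- sleepsiam:::encoder_fwd(tt$fin$model,
                                 rbind(e$samples, e$samples),
                                 train = FALSE)$latent
  expect_equal(lat[1, ], lat[2, ], tolerance = 1e-12)
})

test_that("finetuning updates the sequence block much faster than pretrained blocks", {
  tt <- tiny_trained()
  # compare trainable weights only; batch-norm running statistics move with
  # the data stream no matter the learning rate
  strip_running <- function(p) {
    if (!is.list(p)) return(p)
    nm <- names(p)
    if (!is.null(nm)) p <- p[!(nm %in% c("rm", "rv"))]
    lapply(p, strip_running)
  }
  rel_change <- function(a, b) {
    da <- unlist(strip_running(a))
    db <- unlist(strip_running(b))
    sqrt(sum((da - db)^2)) / sqrt(sum(da^2))
  }
  pre_change <- rel_change(tt$pre$model$params$encoder,
                           tt$fin$model$params$encoder)
  seq_change <- rel_change(tt$pre$staging$params$seq,
                           tt$fin$staging$params$seq)
  expect_lt(pre_change / seq_change, 0.1)
  expect_error(finetune(tt$cohort, tt$pre$model, tt$pre$staging,
                        sleepsiam:::new_train_state(tt$cfg), tt$cfg),
               "pretrain")
})

test_that("checkpoints round-trip to identical predictions and refuse wrong architectures", {
  tt <- tiny_trained()
  path <- withr::local_tempfile(fileext = ".ckpt")
  save_checkpoint(path, tt$fin$model, tt$fin$staging, tt$fin$state)
  ck <- load_checkpoint(path)
  sub <- epoch_subset(tt$cohort, 1:25)
  expect_identical(predict_stages(ck$model, ck$staging, sub, 25L),
                   predict_stages(tt$fin$model, tt$fin$staging, sub, 25L))
  good_arch <- list(variant = "ae", fs = 100, latent_dim = 16L,
                    filters = c(4L, 8L, 8L),
                    feat_dim = tt$fin$staging$feat_dim, hidden = 32L)
  expect_no_error(load_checkpoint(path, good_arch))
  bad_arch <- good_arch
  bad_arch$latent_dim <- 32L
  expect_error(load_checkpoint(path, bad_arch), "mismatch")
})

test_that("cross-validation scores every epoch once and never trains on test subjects", {
  cohort <- generate_cohort(4, 50, fs = 100, seed = 77)
  cfg <- train_config("tiny", epochs_pretrain = 1, epochs_finetune = 1,
                      n_folds = 2, rng_seed = 5L)
  cv <- run_cross_validation(cohort, cfg, variant = "cnn")
  expect_identical(nrow(cv$predictions), n_epochs(cohort))
  key <- paste(cv$predictions$subject, cv$predictions$epoch_index)
  expect_identical(anyDuplicated(key), 0L)
  expect_identical(sum(cv$confusion), n_epochs(cohort))
  expect_identical(unclass(cv$confusion),
                   Reduce(`+`, lapply(cv$fold_confusions, unclass)))
  for (i in seq_along(cv$folds)) {
    expect_length(intersect(cv$states[[i]]$subjects_seen,
                            cv$folds[[i]]$test_subjects), 0)
  }
})
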