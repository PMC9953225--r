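test_that("confusion matrices count correctly", {
  p <- c("W", "N1", "N2", "N3", "REM")
  cm <- confusion_matrix(p, p)
  expect_identical(unname(diag(unclass(cm))), rep(1L, 5))
  expect_identical(sum(cm), 5L)
  set.seed(12)
  tr <- sample(stage_levels(), 100, replace = TRUE)
  pr <- sample(stage_levels(), 100, replace = TRUE)
  cm2 <- confusion_matrix(tr, pr)
  # counting-loop oracle
  for (i in 1:5) {
    for (j in 1:5) {
      expect_identical(unclass(cm2)[i, j],
                       sum(tr == stage_levels()[i] & pr == stage_levels()[j]))
    }
  }
  expect_identical(sum(cm2), 100L)
  expect_error(confusion_matrix(tr, pr[1:99]), "equal")
})

test_that("published confusion tables reproduce their printed per-class metrics", {
  for (tab in published_tables()) {
    cm <- read_confusion_csv(table_csv(tab$csv))
    pc <- per_class_metrics(cm)
    for (col in c("PR", "RE", "F1")) {
      expect_true(all(abs(pc[[col]] - tab$per_class[[col]]) <= 0.15),
                  info = paste(tab$csv, col))
    }
  }
})

test_that("published confusion tables reproduce their printed overall metrics", {
  tabs <- published_tables()
  # AE variant on both datasets: exact at printed precision
  ae_edf <- metrics_report(read_confusion_csv(table_csv(tabs$ae_sleepedf$csv)))
  expect_identical(ae_edf$overall_rounded$ACC, 85.2)
  expect_identical(ae_edf$overall_rounded$MF1, 78.3)
  expect_identical(ae_edf$overall_rounded$kappa, 0.79)
  ae_mass <- metrics_report(read_confusion_csv(table_csv(tabs$ae_mass$csv)))
  expect_identical(ae_mass$overall_rounded$ACC, 87.2)
  expect_identical(ae_mass$overall_rounded$MF1, 82.1)
  expect_identical(ae_mass$overall_rounded$kappa, 0.81)
  # CNN variant: the published summary row differs from its own pooled
  # matrix by < 0.1, so compare at that tolerance
  cnn <- overall_metrics(read_confusion_csv(table_csv(tabs$cnn_sleepedf$csv)))
  expect_equal(cnn$ACC, 84.9, tolerance = 0.15 / 84.9)
  expect_equal(cnn$MF1, 78.0, tolerance = 0.15 / 78)
  expect_equal(round_half_up(cnn$kappa, 2), 0.79)
})

test_that("overall metrics satisfy their defining identities on random matrices", {
  set.seed(13)
  for (rep in 1:10) {
    m <- matrix(rpois(25, 40), 5, 5)
    cm <- as_confusion_matrix(m)
    om <- overall_metrics(cm)
    N <- sum(m)
    acc <- sum(diag(m)) / N
    pe <- sum((rowSums(m) / N) * (colSums(m) / N))
    expect_equal(om$kappa, (acc - pe) / (1 - pe), tolerance = 1e-12)
    expect_equal(om$ACC, 100 * acc, tolerance = 1e-12)
    # micro-averaged recall is the trace-based accuracy
    rec <- diag(m) / rowSums(m)
    expect_equal(sum(rec * rowSums(m)) / N, acc, tolerance = 1e-12)
    # macro-F1 invariant under simultaneous row+column permutation
    p <- sample(5)
    expect_equal(overall_metrics(as_confusion_matrix(m[p, p]))$MF1, om$MF1,
                 tolerance = 1e-12)
  }
  d <- as_confusion_matrix(diag(5) * 10)
  expect_equal(overall_metrics(d)$ACC, 100)
  expect_equal(overall_metrics(d)$kappa, 1)
  expect_true(all(per_class_metrics(d)$F1 == 100))
})

test_that("absent classes yield NA sentinels, never silent zeros", {
  m <- matrix(0L, 5, 5)
  m[2:5, 2:5] <- diag(4) * 3L   # W absent from rows and columns
  pc <- per_class_metrics(as_confusion_matrix(m))
  expect_true(is.na(pc$PR[1]) && is.na(pc$RE[1]) && is.na(pc$F1[1]))
  expect_true(all(pc$F1[2:5] == 100))
  expect_true(is.na(overall_metrics(as_confusion_matrix(m))$MF1))
})

test_that("reports round half-up only at presentation and serialize round-trip", {
  expect_identical(round_half_up(2.25, 1), 2.3)
  expect_identical(round_half_up(87.15, 1), 87.2)
  expect_identical(round_half_up(-2.25, 1), -2.3)
  cm <- read_confusion_csv(table_csv("confusion_siamese_ae_mass.csv"))
  rep1 <- metrics_report(cm)
  path <- withr::local_tempfile(fileext = ".json")
  write_metrics_json(rep1, path)
  back <- jsonlite::read_json(path, simplifyVector = TRUE)
  expect_equal(back$overall$ACC, rep1$overall$ACC, tolerance = 1e-9)
  expect_equal(back$overall$kappa, rep1$overall$kappa, tolerance = 1e-9)
  expect_equal(unname(as.matrix(back$confusion)), unclass(unname(cm)),
               ignore_attr = TRUE)
  rep2 <- metrics_report(cm)
  expect_identical(rep1$per_class, rep2$per_class)
})
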