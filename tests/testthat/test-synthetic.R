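test_that("epoch generation is deterministic under a fixed seed", {
  a <- generate_epoch("W", 100, seed = 1)
  b <- generate_epoch("W", 100, seed = 1)
  expect_identical(a$samples, b$samples)
  expect_false(identical(a$samples, generate_epoch("W", 100, seed = 2)$samples))
  expect_error(generate_epoch("N2", fs = 0), "positive")
})

test_that("stage-conditioned spectra have the expected band structure", {
  n3 <- generate_epoch("N3", 100, seed = 1)$samples
  expect_gt(band_power_fraction(n3, 100, 0.5, 4),
            band_power_fraction(n3, 100, 13, 30))
  w <- generate_epoch("W", 100, seed = 1)$samples
  expect_gt(band_power_fraction(w, 100, 8, 13),
            band_power_fraction(w, 100, 0.5, 4))
})

test_that("spindle bursts add sigma-band power to N2", {
  quiet <- stage_profile(c(theta = 0.8, delta = 0.4, beta = 0.1),
                         amplitude = 40, spindle_burst_rate = 0)
  bursty <- stage_profile(c(theta = 0.8, delta = 0.4, beta = 0.1),
                          amplitude = 40, spindle_burst_rate = 5)
  p_quiet <- band_power_fraction(
    generate_epoch("N2", 100, quiet, seed = 3)$samples, 100, 12, 14)
  p_burst <- band_power_fraction(
    generate_epoch("N2", 100, bursty, seed = 3)$samples, 100, 12, 14)
  expect_gt(p_burst, p_quiet)
})

test_that("transition model is validated and drives the stage sequence", {
  expect_error(transition_model(matrix(1, 5, 5), rep(0.2, 5)),
               "row-stochastic")
  expect_error(transition_model(diag(5), c(0.5, 0.5, 0.5, 0, 0)),
               "probability vector")
  absorbing <- transition_model(diag(5), c(0, 0, 1, 0, 0))
  rec <- generate_recording(30, absorbing, fs = 100, seed = 5)
  expect_true(all(rec$epochs$stage == "N2"))
  expect_length(rec$hypnogram, 30)
  expect_identical(unclass(rec$hypnogram)[1:30], rec$epochs$stage)
})

test_that("long recordings approach the chain's stationary distribution", {
  tm <- default_transition_model()
  # independent stationary-vector oracle: solve pi (P - I) = 0 with sum 1
  A <- rbind(t(tm$matrix) - diag(5), rep(1, 5))
  pi_hat <- qr.solve(A, c(rep(0, 5), 1))
  rec <- generate_recording(200, tm, fs = 100, seed = 7)
  freq <- as.numeric(table(factor(rec$epochs$stage,
                                  levels = stage_levels()))) / 200
  se <- sqrt(pi_hat * (1 - pi_hat) / 200)
  # Markov dependence inflates the iid standard error; self-transition 0.85
  # gives an autocorrelation inflation factor ~ sqrt((1+r)/(1-r)) ~ 3.5
  expect_true(all(abs(freq - pi_hat) <= 3 * 3.5 * se + 1e-9))
  expect_equal(stationary_distribution(tm), setNames(pi_hat, stage_levels()),
               tolerance = 1e-8)
})

test_that("cohorts are reproducible, subject-distinct and stage-complete", {
  a <- generate_cohort(2, 50, fs = 100, seed = 3)
  b <- generate_cohort(2, 50, fs = 100, seed = 3)
  expect_identical(a$x, b$x)
  expect_identical(a$stage, b$stage)
  expect_identical(sort(unique(a$subject_id)), c("s01", "s02"))
  expect_identical(as.integer(table(a$subject_id)), c(50L, 50L))
  expect_error(generate_cohort(1, 50), "at least 2")
  big <- generate_cohort(5, 400, fs = 100, seed = 3)
  expect_setequal(unique(big$stage), stage_levels())
})

test_that("generated spectra carry enough signal for a trivial band-power classifier", {
  cohort <- generate_cohort(4, 125, fs = 100, seed = 31)
  bands <- eeg_bands()
  feat <- t(apply(cohort$x, 1, function(x) {
    vapply(bands, function(b) band_power_fraction(x, 100, b[1], b[2]),
           numeric(1))
  }))
  train <- cohort$subject_id %in% c("s01", "s02")
  templates <- sapply(stage_levels(), function(s) {
    rows <- train & cohort$stage == s
    if (!any(rows)) rep(NA_real_, ncol(feat)) else colMeans(feat[rows, , drop = FALSE])
  })
  pred <- stage_levels()[apply(feat[!train, ], 1, function(f) {
    which.max(apply(templates, 2, function(tpl) -sum((f - tpl)^2)))
  })]
  acc <- mean(pred == cohort$stage[!train])
  expect_gt(acc, 0.20)
})
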