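test_that("wake trimming keeps 30 min of wake on each side of sleep", {
  st <- c(rep("W", 100), rep("N2", 50), rep("W", 100))
  es <- flat_epoch_set(st)
  tr <- trim_wake(hypnogram(st), es)
  expect_length(tr$hypnogram, 170)
  expect_identical(unclass(tr$hypnogram)[1:170],
                   c(rep("W", 60), rep("N2", 50), rep("W", 60)))
  expect_identical(n_epochs(tr$epochs), 170L)
})

test_that("wake trimming leaves short edges and interior wake untouched", {
  st <- c(rep("W", 10), rep("N2", 50), rep("W", 10))
  tr <- trim_wake(hypnogram(st), flat_epoch_set(st))
  expect_length(tr$hypnogram, 70)

  st2 <- c(rep("W", 70), "N2", rep("W", 5), "N2", rep("W", 70))
  tr2 <- trim_wake(hypnogram(st2), flat_epoch_set(st2))
  # interior 5 W epochs retained; edges cut to 60
  expect_length(tr2$hypnogram, 60 + 1 + 5 + 1 + 60)
  expect_identical(sum(unclass(tr2$hypnogram) == "N2"), 2L)
})

test_that("wake trimming never removes sleep and warns on all-wake input", {
  set.seed(11)
  for (i in 1:5) {
    st <- sample(stage_levels(), 120, replace = TRUE,
                 prob = c(0.5, 0.1, 0.2, 0.1, 0.1))
    tr <- trim_wake(hypnogram(st), flat_epoch_set(st))
    expect_identical(sum(unclass(tr$hypnogram) != "W"), sum(st != "W"))
    expect_lte(length(tr$hypnogram), length(st))
  }
  st_w <- rep("W", 80)
  expect_warning(tr <- trim_wake(hypnogram(st_w), flat_epoch_set(st_w)),
                 "only wake")
  expect_length(tr$hypnogram, 80)
})

test_that("pair sampling hits the exact same/different split deterministically", {
  set.seed(2)
  st <- sample(stage_levels(), 100, replace = TRUE)
  es <- flat_epoch_set(st)
  p <- sample_pairs(es, pair_sampler_config(50, 0.5, seed = 1))
  expect_identical(nrow(p), 50L)
  expect_identical(sum(p$same_stage), 25L)
  expect_identical(p$same_stage,
                   (es$stage[p$first] == es$stage[p$second]))
  expect_true(all(p$first != p$second))
  p2 <- sample_pairs(es, pair_sampler_config(50, 0.5, seed = 1))
  expect_identical(p, p2)
  p3 <- sample_pairs(es, pair_sampler_config(10, 0.3, seed = 4))
  expect_identical(sum(p3$same_stage), 3L)
})

test_that("pair sampling rejects degenerate inputs", {
  one_stage <- flat_epoch_set(rep("N2", 10))
  expect_error(sample_pairs(one_stage, pair_sampler_config(10, 0.5)),
               "only one stage")
  # all-same pairs from a single stage are fine
  p <- sample_pairs(one_stage, pair_sampler_config(10, 1, seed = 2))
  expect_true(all(p$same_stage))
  expect_error(sample_pairs(flat_epoch_set("W"), pair_sampler_config(5, 0.5)),
               "at least 2")
  expect_error(pair_sampler_config(0, 0.5), "n_pairs")
})

test_that("sequence windows are non-overlapping, complete and subject-bound", {
  es <- flat_epoch_set(rep("N2", 60))
  s <- make_sequences(es, 25L)
  expect_length(s, 2)
  expect_identical(s[[1]][1:25], 1:25)
  expect_identical(s[[2]][1:25], 26:50)

  expect_length(make_sequences(flat_epoch_set(rep("W", 25)), 25L), 1)

  two <- epoch_rbind(list(flat_epoch_set(rep("N2", 30), "a"),
                          flat_epoch_set(rep("N3", 30), "b")))
  s2 <- make_sequences(two, 25L)
  expect_length(s2, 2)
  expect_identical(vapply(s2, attr, character(1), "subject_id"), c("a", "b"))
  for (w in s2) expect_length(unique(two$subject_id[w]), 1L)
  expect_error(make_sequences(es, 0L), "seq_len")
})
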