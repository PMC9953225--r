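test_that("euclidean distance matches the naive sum-of-squares oracle", {
  expect_identical(euclidean_distance(1:5, 1:5), 0)
  expect_equal(euclidean_distance(c(0, 0), c(3, 4)), 5)
  set.seed(1)
  a <- rnorm(50); b <- rnorm(50)
  oracle <- sqrt(sum(vapply(seq_along(a), function(i) (a[i] - b[i])^2,
                            numeric(1))))
  expect_equal(euclidean_distance(a, b), oracle, tolerance = 1e-9)
  expect_error(euclidean_distance(1:3, 1:4), "equal length")
})

test_that("contrastive pair loss satisfies its closed forms", {
  m <- 7400
  expect_identical(pair_contrastive_loss(0, TRUE, m), 0)
  expect_identical(pair_contrastive_loss(m, FALSE, m), 0)
  expect_identical(pair_contrastive_loss(m + 100, FALSE, m), 0)
  expect_identical(pair_contrastive_loss(0, FALSE, m), 0.5 * m^2)
  expect_identical(0.5 * m^2, 27380000)
  expect_equal(pair_contrastive_loss(3, TRUE, m), 4.5)
  expect_error(pair_contrastive_loss(-1, TRUE, m), "nonnegative")
  expect_error(pair_contrastive_loss(1, TRUE, 0), "positive")
})

test_that("contrastive pair loss is continuous at the margin and has the right slopes", {
  m <- 5
  eps <- 1e-7
  expect_equal(pair_contrastive_loss(m - eps, FALSE, m),
               pair_contrastive_loss(m + eps, FALSE, m), tolerance = 1e-10)
  # slope wrt d: nonnegative for similar pairs, nonpositive below the margin
  # for dissimilar pairs
  num_slope <- function(d, same) {
    (pair_contrastive_loss(d + eps, same, m) -
       pair_contrastive_loss(d - eps, same, m)) / (2 * eps)
  }
  for (d in c(0.5, 1, 3, 4.9)) {
    expect_gte(num_slope(d, TRUE), 0)
    expect_lte(num_slope(d, FALSE), 0)
  }
})

test_that("batch contrastive loss is the sum over pairs of the closed form", {
  set.seed(3)
  lat <- function() rnorm(8)
  pairs <- lapply(1:10, function(i) {
    list(a = lat(), b = lat(), same_stage = i %% 2 == 0)
  })
  m <- 4
  oracle <- 0
  for (p in pairs) {
    d <- sqrt(sum((p$a - p$b)^2))
    oracle <- oracle + if (p$same_stage) 0.5 * d^2 else
      0.5 * max(0, m - d)^2
  }
  expect_equal(contrastive_loss(pairs, m), oracle, tolerance = 1e-6)
  one <- pairs[1]
  d1 <- euclidean_distance(one[[1]]$a, one[[1]]$b)
  expect_equal(contrastive_loss(one, m),
               pair_contrastive_loss(d1, one[[1]]$same_stage, m))
  same0 <- list(list(a = 1:3, b = 1:3, same_stage = TRUE))
  expect_identical(contrastive_loss(same0, m), 0)
  expect_error(contrastive_loss(list(), m), "nonempty")
})

test_that("cross-entropy matches closed forms and a per-element loop oracle", {
  labels <- c("W", "N2", "REM")
  onehot <- diag(5)[stage_index(labels) + 1L, ]
  expect_equal(cross_entropy(onehot, labels), 0)
  unif <- matrix(0.2, 3, 5)
  expect_equal(cross_entropy(unif, labels), log(5), tolerance = 1e-12)
  set.seed(4)
  Z <- matrix(rexp(20 * 5), 20)
  P <- Z / rowSums(Z)
  lab <- sample(stage_levels(), 20, replace = TRUE)
  oracle <- 0
  for (i in 1:20) {
    for (k in 1:5) {
      y <- as.numeric(stage_index(lab[i]) + 1L == k)
      oracle <- oracle - y * log(P[i, k])
    }
  }
  expect_equal(cross_entropy(P, lab), oracle / 20, tolerance = 1e-9)
  zp <- matrix(c(0, 0.5, 0.5, 0, 0), 1)
  expect_warning(v <- cross_entropy(zp, "W"), "clamped")
  expect_equal(v, -log(1e-12))
})

test_that("1-D W2 uses the optimal monotone coupling", {
  expect_identical(wasserstein2_1d(c(3, 1, 2), c(2, 3, 1)), 0)
  expect_equal(wasserstein2_1d(c(0, 1), c(2, 3)), 2)
  # brute-force assignment oracle over all permutations at n = 5
  set.seed(5)
  a <- rnorm(5); b <- rnorm(5)
  perms <- expand.grid(rep(list(1:5), 5))
  perms <- perms[apply(perms, 1, function(p) length(unique(p)) == 5), ]
  oracle <- sqrt(min(apply(perms, 1, function(p) mean((a - b[unlist(p)])^2))))
  expect_equal(wasserstein2_1d(a, b), oracle, tolerance = 1e-9)
  # sorted-coupling formula at n = 30
  a30 <- rnorm(30); b30 <- rnorm(30)
  expect_equal(wasserstein2_1d(a30, b30),
               sqrt(mean((sort(a30) - sort(b30))^2)), tolerance = 1e-12)
  expect_error(wasserstein2_1d(numeric(0), numeric(0)), "nonempty")
  expect_error(wasserstein2_1d(1:3, 1:4), "equal size")
})

test_that("max-sliced W2 recovers translations and dense-grid maxima", {
  set.seed(6)
  u <- matrix(rnorm(40), 20, 2)
  expect_equal(as.numeric(max_sliced_w2(u, u, seed = 1)), 0)
  t_vec <- c(2, -1, 0.5)
  u3 <- matrix(rnorm(60), 20, 3)
  v3 <- sweep(u3, 2, t_vec, `+`)
  expect_equal(as.numeric(max_sliced_w2(u3, v3, 64, 50, seed = 2)),
               sqrt(sum(t_vec^2)), tolerance = 0.01)
  # dense-grid oracle in d = 2
  v <- matrix(rnorm(40, sd = 2), 20, 2)
  ang <- seq(0, pi, length.out = 1e5)
  grid_max <- 0
  for (chunk in split(ang, ceiling(seq_along(ang) / 5000))) {
    W <- rbind(cos(chunk), sin(chunk))
    pu <- apply(u %*% W, 2, sort)
    pv <- apply(v %*% W, 2, sort)
    grid_max <- max(grid_max, sqrt(colMeans((pu - pv)^2)))
  }
  found <- as.numeric(max_sliced_w2(u, v, 64, 50, seed = 3))
  expect_gte(found, grid_max * 0.99)
  expect_lte(found, grid_max * 1.001)
})

test_that("max-sliced W2 is symmetric, scales linearly and grows with nested directions", {
  set.seed(7)
  u <- matrix(rnorm(30), 15, 2); v <- matrix(rnorm(30), 15, 2)
  expect_equal(as.numeric(max_sliced_w2(u, v, 32, 20, seed = 4)),
               as.numeric(max_sliced_w2(v, u, 32, 20, seed = 4)),
               tolerance = 1e-9)
  base <- as.numeric(max_sliced_w2(u, v, 32, 20, seed = 4))
  for (s in c(0.5, 2)) {
    expect_equal(as.numeric(max_sliced_w2(s * u, s * v, 32, 20, seed = 4)),
                 s * base, tolerance = 1e-8)
  }
  v16 <- as.numeric(max_sliced_w2(u, v, 16, 0, seed = 9))
  v64 <- as.numeric(max_sliced_w2(u, v, 64, 0, seed = 9))
  expect_gte(v64, v16)
  expect_error(max_sliced_w2(u, matrix(rnorm(30), 10, 3)), "dimension")
  expect_error(max_sliced_w2(u, v[1:10, ]), "cardinality")
})

test_that("combined distance decomposes into its Euclidean and max-sliced parts", {
  set.seed(8)
  U <- matrix(rnorm(5 * 12), 5, 12)
  expect_equal(suppressMessages(combined_distance(U, U)), 0)
  V <- U + matrix(rnorm(5 * 12, sd = 0.3), 5, 12)
  expect_equal(combined_distance(U, V, 32, 20, seed = 5),
               mean(sqrt(rowSums((U - V)^2))) +
                 as.numeric(max_sliced_w2(U, V, 32, 20, seed = 5)),
               tolerance = 1e-6)
  # single-epoch fallback: constant shift c gives |c|*sqrt(L) + |c|
  L <- 16; cc <- 0.7
  u1 <- rnorm(L); v1 <- u1 + cc
  expect_message(d1 <- combined_distance(u1, v1), "falls back")
  expect_equal(d1, cc * sqrt(L) + cc, tolerance = 1e-9)
})

test_that("loss breakdowns add their components exactly", {
  expect_identical(loss_cnn(0, 0)$total, 0)
  expect_identical(loss_cnn(1.0, 2.5)$total, 3.5)
  expect_identical(loss_cnn(1.0, 2.5)$reconstruction, 0)
  expect_identical(loss_ae(0, 0, 0)$total, 0)
  set.seed(9)
  for (i in 1:5) {
    v <- runif(3)
    b <- loss_ae(v[1], v[2], v[3])
    expect_equal(b$total,
                 b$cross_entropy + b$contrastive + b$reconstruction,
                 tolerance = 1e-9)
  }
  expect_error(loss_cnn(-1, 0), "nonnegative")
})
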