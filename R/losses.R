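# Distance metrics and the composite training losses.
#
# Conventions: same-stage pairs are pulled together (loss = d^2/2), and
# different-stage pairs are pushed beyond the margin m
# (loss = max(0, m - d)^2 / 2). The contrastive loss over a batch is the SUM
# over its pairs, not the mean, so batch size enters the loss scale.
# Cross-entropy is averaged over epochs. The autoencoder reconstruction
# distance is Euclidean + max-sliced Wasserstein-2.

#' Euclidean (L2) distance between two vectors
#' @param a,b numeric vectors of equal length.
#' @return Nonnegative scalar `||a - b||_2`.
#' @export
euclidean_distance <- function(a, b) {
  if (length(a) != length(b)) stop("vectors must have equal length")
  sqrt(sum((a - b)^2))
}

#' Contrastive loss of a single pair
#'
#' Same-stage pairs are penalized by half the squared latent distance;
#' different-stage pairs by half the squared margin shortfall
#' `max(0, m - d)`. The two branches meet continuously at `d = m`.
#'
#' @param d nonnegative latent distance.
#' @param same_stage logical: do the two epochs share a stage?
#' @param m positive margin.
#' @return Nonnegative scalar loss.
#' @export
#' @examples
#' pair_contrastive_loss(0, same_stage = FALSE, m = 7400)  # m^2 / 2
pair_contrastive_loss <- function(d, same_stage, m) {
  if (any(d < 0)) stop("distance must be nonnegative")
  if (m <= 0) stop("margin m must be positive")
  ifelse(same_stage, 0.5 * d^2, 0.5 * pmax(0, m - d)^2)
}

#' Contrastive loss of a batch of latent pairs
#'
#' Sums [pair_contrastive_loss()] over all pairs, with each pair's distance
#' computed by [euclidean_distance()] of its two latent vectors.
#'
#' @param pairs list of pairs; each element a list with numeric vectors `a`
#'   and `b` (the two latents) and logical `same_stage`.
#' @param m positive margin.
#' @return Nonnegative scalar: the summed loss.
#' @export
contrastive_loss <- function(pairs, m) {
  if (length(pairs) == 0L) stop("pair list must be nonempty")
  tot <- 0
  for (p in pairs) {
    d <- euclidean_distance(p$a, p$b)
    tot <- tot + pair_contrastive_loss(d, isTRUE(p$same_stage), m)
  }
  tot
}

#' Multi-class cross-entropy over epochs
#'
#' Mean over epochs of minus the log predicted probability of the true
#' stage. Zero probabilities at the true class are clamped at 1e-12 and
#' reported via a warning.
#'
#' @param probs numeric matrix (`n x 5`, rows summing to 1) or list of
#'   length-5 probability vectors.
#' @param labels character vector of true stage codes, length `n`.
#' @return Nonnegative scalar loss.
#' @export
cross_entropy <- function(probs, labels) {
  if (is.list(probs)) probs <- do.call(rbind, probs)
  probs <- as.matrix(probs)
  n <- nrow(probs)
  if (n < 1L || length(labels) != n) {
    stop("probs and labels must have the same positive length")
  }
  if (ncol(probs) != 5L) stop("probabilities must have 5 columns")
  p_true <- probs[cbind(seq_len(n), stage_index(labels) + 1L)]
  if (any(p_true <= 0)) {
    warning("zero predicted probability at a true class; clamped at 1e-12")
    p_true <- pmax(p_true, 1e-12)
  }
  -mean(log(p_true))
}

#' One-dimensional Wasserstein-2 distance between equal-size samples
#'
#' Uses the optimal monotone coupling: the square root of the mean squared
#' difference of the sorted samples. Permutation-invariant in each argument.
#'
#' @param a,b numeric vectors with the same (positive) number of samples.
#' @return Nonnegative scalar.
#' @export
#' @examples
#' wasserstein2_1d(c(0, 1), c(2, 3))  # 2: every mass moves by 2
wasserstein2_1d <- function(a, b) {
  if (length(a) == 0L || length(b) == 0L) stop("sample sets must be nonempty")
  if (length(a) != length(b)) stop("sample sets must have equal size")
  sqrt(mean((sort(a) - sort(b))^2))
}

# Squared 1-D W2 of projections along direction w, plus its gradient in w
# (sort permutations held fixed, which is exact a.e.).
msw_objective <- function(U, V, w) {
  pu <- drop(U %*% w); pv <- drop(V %*% w)
  ou <- order(pu); ov <- order(pv)
  diff <- pu[ou] - pv[ov]
  list(value = mean(diff^2),
       grad = drop(2 * crossprod(diff, U[ou, , drop = FALSE] -
                                   V[ov, , drop = FALSE])) / nrow(U))
}

#' Max-sliced Wasserstein-2 distance between two point sets
#'
#' Approximates the supremum over unit directions of the 1-D W2 distance
#' between the projections of `u` and `v`. The search takes the best of
#' `n_directions` random unit directions (drawn sequentially, so enlarging
#' `n_directions` under one seed only extends the candidate set and the
#' result never decreases), then runs `n_refine` projected gradient-ascent
#' steps with backtracking, keeping the best direction seen.
#'
#' @param u,v numeric matrices with one point per row; equal dimensions and
#'   equal row counts. Plain vectors are treated as single-column matrices.
#' @param n_directions number of random starting directions (>= 1).
#' @param n_refine gradient-ascent refinement steps.
#' @param seed integer RNG seed for the direction draw.
#' @return Nonnegative scalar distance.
#' @export
max_sliced_w2 <- function(u, v, n_directions = 64L, n_refine = 50L,
                          seed = 1L) {
  U <- if (is.matrix(u)) u else matrix(u, ncol = 1L)
  V <- if (is.matrix(v)) v else matrix(v, ncol = 1L)
  if (ncol(U) != ncol(V)) stop("point sets must share one dimension")
  if (nrow(U) != nrow(V)) stop("point sets must have equal cardinality")
  if (n_directions < 1L) stop("n_directions must be >= 1")
  d <- ncol(U)
  if (d == 1L) return(wasserstein2_1d(U[, 1L], V[, 1L]))
  best <- list(value = -Inf, w = NULL)
  with_seed(seed, {
    for (k in seq_len(n_directions)) {
      w <- stats::rnorm(d)
      w <- w / sqrt(sum(w^2))
      val <- msw_objective(U, V, w)$value
      if (val > best$value) best <- list(value = val, w = w)
    }
  })
  w <- best$w
  if (best$value > 0 && n_refine > 0L) {
    eta <- 0.1
    for (it in seq_len(n_refine)) {
      ob <- msw_objective(U, V, w)
      gn <- sqrt(sum(ob$grad^2))
      if (gn < 1e-14) break
      step <- eta * ob$grad / gn
      w_new <- w + step
      w_new <- w_new / sqrt(sum(w_new^2))
      val_new <- msw_objective(U, V, w_new)$value
      if (val_new > best$value) {
        best <- list(value = val_new, w = w_new)
        w <- w_new
      } else {
        eta <- eta / 2
        if (eta < 1e-10) break
      }
    }
  }
  attr_w <- best$w
  out <- sqrt(max(best$value, 0))
  attr(out, "direction") <- attr_w
  out
}

#' Combined Euclidean + max-sliced-W2 distance between two epoch batches
#'
#' The reconstruction distance of the autoencoder loss. The Euclidean term
#' is the per-epoch L2 distance averaged over the batch; the max-sliced term
#' treats the batch's epochs as point sets in sample space. With fewer than
#' two epochs per batch the max-sliced term degenerates to a single point
#' per set, so it falls back to the 1-D W2 between the two vectors' samples
#' (reported via a message).
#'
#' @param u,v numeric vectors (one epoch) or matrices (one epoch per row) of
#'   matching shape.
#' @param n_directions,n_refine,seed passed to [max_sliced_w2()].
#' @return Nonnegative scalar distance.
#' @export
combined_distance <- function(u, v, n_directions = 64L, n_refine = 50L,
                              seed = 1L) {
  U <- if (is.matrix(u)) u else matrix(u, nrow = 1L)
  V <- if (is.matrix(v)) v else matrix(v, nrow = 1L)
  if (!all(dim(U) == dim(V))) stop("batches must have matching shapes")
  euc <- mean(sqrt(rowSums((U - V)^2)))
  if (nrow(U) >= 2L) {
    msw <- as.numeric(max_sliced_w2(U, V, n_directions, n_refine, seed))
  } else {
    message("single-epoch batch: max-sliced term falls back to 1-D W2 over samples")
    msw <- wasserstein2_1d(U[1L, ], V[1L, ])
  }
  euc + msw
}

#' Loss breakdown of the composite training objective
#'
#' @param cross_entropy,contrastive,reconstruction nonnegative components.
#' @return An object of class `"loss_breakdown"` with fields `total`,
#'   `cross_entropy`, `contrastive`, `reconstruction`;
#'   `total = cross_entropy + contrastive + reconstruction`.
#' @export
loss_breakdown <- function(cross_entropy, contrastive, reconstruction = 0) {
  if (any(c(cross_entropy, contrastive, reconstruction) < 0)) {
    stop("loss components must be nonnegative")
  }
  structure(list(total = cross_entropy + contrastive + reconstruction,
                 cross_entropy = cross_entropy, contrastive = contrastive,
                 reconstruction = reconstruction),
            class = "loss_breakdown")
}

#' @export
print.loss_breakdown <- function(x, ...) {
  cat(sprintf("loss total %.6g = CE %.6g + contrastive %.6g + reconstruction %.6g\n",
              x$total, x$cross_entropy, x$contrastive, x$reconstruction))
  invisible(x)
}

#' Composite loss of the Siamese-CNN variant (no reconstruction term)
#' @param ce cross-entropy component (>= 0).
#' @param ct contrastive component (>= 0).
#' @return A `loss_breakdown` with zero reconstruction component.
#' @export
loss_cnn <- function(ce, ct) loss_breakdown(ce, ct, 0)

#' Composite loss of the Siamese-AE variant
#' @param reconstruction_d combined reconstruction distance (>= 0).
#' @param ce cross-entropy component (>= 0).
#' @param ct contrastive component (>= 0).
#' @return A `loss_breakdown`.
#' @export
loss_ae <- function(reconstruction_d, ce, ct) {
  loss_breakdown(ce, ct, reconstruction_d)
}
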