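#' Configuration for Siamese pair sampling
#'
#' @param n_pairs number of pairs to draw (>= 1).
#' @param same_fraction fraction of pairs whose two epochs share a stage;
#'   the split is exact: `round(n_pairs * same_fraction)` same-stage pairs.
#' @param seed integer RNG seed.
#' @return An object of class `"pair_sampler_config"`.
#' @export
pair_sampler_config <- function(n_pairs, same_fraction = 0.5, seed = 1) {
  if (n_pairs < 1) stop("n_pairs must be >= 1")
  if (same_fraction < 0 || same_fraction > 1) {
    stop("same_fraction must lie in [0, 1]")
  }
  structure(list(n_pairs = as.integer(n_pairs),
                 same_fraction = same_fraction, seed = as.integer(seed)),
            class = "pair_sampler_config")
}

#' Trim excess wake at the edges of a recording
#'
#' Only `max_wake_minutes` of wake are retained before the first and after
#' the last non-wake epoch; wake epochs inside the sleep period are never
#' touched. With 30-s epochs the default keeps at most 60 leading and 60
#' trailing W epochs adjacent to sleep.
#'
#' @param hyp a `hypnogram`.
#' @param epochs the matching `epoch_set` (same length, same order).
#' @param max_wake_minutes minutes of wake retained on each side (default 30).
#' @return A list with the trimmed `hypnogram` and `epochs`.
#' @export
trim_wake <- function(hyp, epochs, max_wake_minutes = 30) {
  stopifnot(inherits(hyp, "hypnogram"), inherits(epochs, "epoch_set"))
  n <- length(hyp)
  if (n != n_epochs(epochs)) stop("hypnogram and epochs must be aligned")
  if (!identical(unclass(hyp)[seq_len(n)], epochs$stage)) {
    stop("hypnogram labels do not match epoch labels")
  }
  keep_w <- floor(max_wake_minutes * 60 / 30)
  nonw <- which(unclass(hyp) != "W")
  if (length(nonw) == 0L) {
    warning("recording contains only wake; nothing to trim against")
    return(list(hypnogram = hyp, epochs = epochs))
  }
  lo <- max(1L, min(nonw) - keep_w)
  hi <- min(n, max(nonw) + keep_w)
  idx <- lo:hi
  list(hypnogram = hypnogram(unclass(hyp)[idx], attr(hyp, "subject_id")),
       epochs = epoch_subset(epochs, idx))
}

#' Sample labeled epoch pairs for contrastive training
#'
#' Draws `n_pairs` pairs with an exact same-/different-stage split
#' (`round(n_pairs * same_fraction)` same-stage). Same-stage pairs pick two
#' distinct epochs of one stage; different-stage pairs first pick an
#' unordered stage pair uniformly among stages present (so majority classes
#' do not dominate the negatives), then one epoch from each. Pairs are drawn
#' with replacement across the set but an epoch is never paired with itself.
#'
#' @param epochs an `epoch_set`.
#' @param config a `pair_sampler_config`.
#' @return A data.frame with integer columns `first`, `second` (row indices
#'   into `epochs`) and logical `same_stage`. Use [pair_records()] to
#'   materialize `epoch_pair` objects.
#' @export
sample_pairs <- function(epochs, config) {
  stopifnot(inherits(epochs, "epoch_set"),
            inherits(config, "pair_sampler_config"))
  n <- n_epochs(epochs)
  if (n < 2L) stop("need at least 2 epochs to form pairs")
  st <- epochs$stage
  present <- unique(st)
  n_same <- round(config$n_pairs * config$same_fraction)
  n_diff <- config$n_pairs - n_same
  if (n_diff > 0 && length(present) < 2L) {
    stop("only one stage present: cannot draw different-stage pairs")
  }
  multi <- names(Filter(function(k) k >= 2L, table(st)))
  if (n_same > 0 && length(multi) == 0L) {
    stop("no stage has two epochs: cannot draw same-stage pairs")
  }
  by_stage <- split(seq_len(n), st)
  with_seed(config$seed, {
    first <- integer(0); second <- integer(0); same <- logical(0)
    if (n_same > 0) {
      elig <- which(st %in% multi)
      i <- elig[sample.int(length(elig), n_same, replace = TRUE)]
      j <- vapply(i, function(a) {
        cand <- setdiff(by_stage[[st[a]]], a)
        cand[sample.int(length(cand), 1L)]
      }, integer(1))
      first <- c(first, i); second <- c(second, j)
      same <- c(same, rep(TRUE, n_same))
    }
    if (n_diff > 0) {
      combos <- utils::combn(sort(present), 2L)
      pick <- sample.int(ncol(combos), n_diff, replace = TRUE)
      i <- integer(n_diff); j <- integer(n_diff)
      for (p in seq_len(n_diff)) {
        a <- by_stage[[combos[1L, pick[p]]]]
        b <- by_stage[[combos[2L, pick[p]]]]
        i[p] <- a[sample.int(length(a), 1L)]
        j[p] <- b[sample.int(length(b), 1L)]
      }
      first <- c(first, i); second <- c(second, j)
      same <- c(same, rep(FALSE, n_diff))
    }
    data.frame(first = first, second = second, same_stage = same)
  })
}

#' Materialize one sampled pair as an `epoch_pair`
#' @param epochs the `epoch_set` the pairs index into.
#' @param pairs data.frame from [sample_pairs()].
#' @param k row of `pairs` to materialize.
#' @return An `epoch_pair`.
#' @export
pair_records <- function(epochs, pairs, k) {
  epoch_pair(epoch_at(epochs, pairs$first[k]),
             epoch_at(epochs, pairs$second[k]))
}

#' Cut epochs into fixed-length training sequences
#'
#' Non-overlapping consecutive windows of `seq_len` epochs, taken per
#' subject in `epoch_index` order; a final partial window is dropped and
#' windows never span two subjects.
#'
#' @param epochs an `epoch_set`.
#' @param seq_len window length in epochs (default 25).
#' @return A list of integer vectors of row indices into `epochs`, each with
#'   a `"subject_id"` attribute.
#' @export
make_sequences <- function(epochs, seq_len = 25L) {
  stopifnot(inherits(epochs, "epoch_set"))
  if (seq_len < 1L) stop("seq_len must be >= 1")
  out <- list()
  for (sid in unique(epochs$subject_id)) {
    rows <- which(epochs$subject_id == sid)
    rows <- rows[order(epochs$epoch_index[rows])]
    nw <- length(rows) %/% seq_len
    for (w in seq_len(nw)) {
      idx <- rows[((w - 1L) * seq_len + 1L):(w * seq_len)]
      attr(idx, "subject_id") <- sid
      out[[length(out) + 1L]] <- idx
    }
  }
  out
}
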