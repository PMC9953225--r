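#' A single 30-second EEG epoch
#'
#' Constructs and validates one labeled 30-s epoch of single-channel EEG.
#' Amplitudes are conventionally in microvolts but are not rescaled by the
#' package; the contrastive margin `m` is the only scale-sensitive parameter.
#'
#' @param samples numeric vector of length `fs * 30`, all finite.
#' @param fs sampling rate in Hz (positive).
#' @param stage stage code, one of [stage_levels()].
#' @param subject_id subject identifier (coerced to character).
#' @param epoch_index 0-based position of the epoch within its recording.
#' @return An object of class `"epoch_record"`.
#' @export
epoch_record <- function(samples, fs, stage, subject_id = "s1",
                         epoch_index = 0L) {
  fs <- as.numeric(fs)
  if (length(fs) != 1L || !is.finite(fs) || fs <= 0) {
    stop("fs must be a single positive number")
  }
  samples <- as.numeric(samples)
  if (length(samples) != fs * 30) {
    stop("epoch must contain exactly fs * 30 = ", fs * 30,
         " samples, got ", length(samples))
  }
  if (!all(is.finite(samples))) stop("epoch samples must all be finite")
  stage <- match.arg(stage, stage_levels())
  structure(list(samples = samples, fs = fs, stage = stage,
                 subject_id = as.character(subject_id),
                 epoch_index = as.integer(epoch_index)),
            class = "epoch_record")
}

#' @export
print.epoch_record <- function(x, ...) {
  cat(sprintf("<epoch_record> subject %s, epoch %d, stage %s, %d samples @ %g Hz\n",
              x$subject_id, x$epoch_index, x$stage, length(x$samples), x$fs))
  invisible(x)
}

#' An ordered sequence of stage labels for one recording
#'
#' @param stages character vector of stage codes in recording order.
#' @param subject_id subject identifier.
#' @return An object of class `"hypnogram"` (a character vector with a
#'   `subject_id` attribute).
#' @export
hypnogram <- function(stages, subject_id = "s1") {
  if (length(stages) == 0L) stop("hypnogram must be nonempty")
  stage_index(stages)  # validates codes
  structure(as.character(stages), subject_id = as.character(subject_id),
            class = "hypnogram")
}

#' @export
print.hypnogram <- function(x, ...) {
  cat(sprintf("<hypnogram> subject %s, %d epochs (%s)\n",
              attr(x, "subject_id"), length(x),
              paste(sprintf("%s:%d", names(table(unclass(x))),
                            as.integer(table(unclass(x)))), collapse = " ")))
  invisible(x)
}

#' A matrix-backed set of labeled epochs
#'
#' The package's working container: `n` epochs as the rows of an
#' `n x (fs*30)` matrix, with parallel stage, subject and index vectors.
#' All preprocessing, pairing and training operate on this container.
#'
#' @param x numeric matrix, one epoch per row.
#' @param stage character vector of stage codes, length `nrow(x)`.
#' @param subject_id character vector (recycled if length 1).
#' @param epoch_index integer vector of 0-based within-subject positions;
#'   defaults to 0..(n-1) within each subject in row order.
#' @param fs sampling rate in Hz.
#' @return An object of class `"epoch_set"`.
#' @export
epoch_set <- function(x, stage, subject_id = "s1", epoch_index = NULL,
                      fs = 100) {
  x <- as.matrix(x)
  n <- nrow(x)
  if (ncol(x) != fs * 30) stop("epoch_set rows must have fs * 30 columns")
  if (length(stage) != n) stop("stage must have one entry per epoch")
  stage_index(stage)
  subject_id <- rep_len(as.character(subject_id), n)
  if (is.null(epoch_index)) {
    epoch_index <- stats::ave(seq_len(n), subject_id,
                              FUN = function(i) seq_along(i) - 1L)
  }
  structure(list(x = x, stage = as.character(stage), subject_id = subject_id,
                 epoch_index = as.integer(epoch_index), fs = as.numeric(fs)),
            class = "epoch_set")
}

#' @export
print.epoch_set <- function(x, ...) {
  tab <- table(factor(x$stage, levels = stage_levels()))
  cat(sprintf("<epoch_set> %d epochs, %d subject(s), fs = %g Hz\n",
              nrow(x$x), length(unique(x$subject_id)), x$fs))
  cat("  stages:", paste(sprintf("%s=%d", names(tab), as.integer(tab)),
                         collapse = " "), "\n")
  invisible(x)
}

#' Number of epochs in an epoch set
#' @param es an `epoch_set`.
#' @return Integer count.
#' @export
n_epochs <- function(es) nrow(es$x)

#' Subset an epoch set by row indices
#' @param es an `epoch_set`.
#' @param i integer row indices.
#' @return A new `epoch_set`.
#' @export
epoch_subset <- function(es, i) {
  epoch_set(es$x[i, , drop = FALSE], es$stage[i], es$subject_id[i],
            es$epoch_index[i], es$fs)
}

#' Combine epoch sets from several subjects
#' @param ... `epoch_set` objects with identical `fs`.
#' @return A pooled `epoch_set`.
#' @export
epoch_rbind <- function(...) {
  sets <- list(...)
  if (length(sets) == 1L && is.list(sets[[1]]) && !inherits(sets[[1]], "epoch_set")) {
    sets <- sets[[1]]
  }
  fs <- unique(vapply(sets, function(s) s$fs, numeric(1)))
  if (length(fs) != 1L) stop("all epoch sets must share one sampling rate")
  epoch_set(do.call(rbind, lapply(sets, function(s) s$x)),
            unlist(lapply(sets, function(s) s$stage)),
            unlist(lapply(sets, function(s) s$subject_id)),
            unlist(lapply(sets, function(s) s$epoch_index)), fs)
}

#' Extract one epoch as an `epoch_record`
#' @param es an `epoch_set`.
#' @param i row index.
#' @return An `epoch_record`.
#' @export
epoch_at <- function(es, i) {
  epoch_record(es$x[i, ], es$fs, es$stage[i], es$subject_id[i],
               es$epoch_index[i])
}

#' A Siamese training pair of epochs
#'
#' The similarity label is derived from the two stage labels by the
#' constructor, so `same_stage == (first$stage == second$stage)` always holds.
#'
#' @param first,second `epoch_record` objects.
#' @return An object of class `"epoch_pair"` with fields `first`, `second`,
#'   `same_stage`.
#' @export
epoch_pair <- function(first, second) {
  stopifnot(inherits(first, "epoch_record"), inherits(second, "epoch_record"))
  if (length(first$samples) != length(second$samples)) {
    stop("paired epochs must have equal length")
  }
  structure(list(first = first, second = second,
                 same_stage = identical(first$stage, second$stage)),
            class = "epoch_pair")
}

#' Class probabilities over the five stages
#'
#' Validates a probability vector: five entries in `[0,1]` summing to 1
#' within 1e-6.
#'
#' @param probs numeric vector of length 5.
#' @return Named numeric vector (names = [stage_levels()]).
#' @export
class_probabilities <- function(probs) {
  probs <- as.numeric(probs)
  if (length(probs) != 5L) stop("need exactly 5 class probabilities")
  if (any(probs < 0 | probs > 1)) stop("probabilities must lie in [0,1]")
  if (abs(sum(probs) - 1) > 1e-6) stop("probabilities must sum to 1")
  stats::setNames(probs, stage_levels())
}
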