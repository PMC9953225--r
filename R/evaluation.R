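# Evaluation: per-class precision/recall/F1, overall accuracy, macro-F1 and
# Cohen's kappa from a (summed) 5x5 confusion matrix. Macro-F1 is computed
# from full-precision per-class F1 values; rounding (half-up, one decimal)
# happens only at presentation.

#' Round half away from zero
#'
#' Presentation rounding matching the convention of printed results tables
#' (0.05 rounds up), unlike base R's round-half-to-even.
#'
#' @param x numeric vector.
#' @param digits decimal places.
#' @return Rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 1) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Build a 5x5 confusion matrix from true and predicted stages
#'
#' Rows are the human-scored (true) stages, columns the model's
#' predictions, both in [stage_levels()] order.
#'
#' @param true,predicted character vectors of stage codes, equal length.
#' @return An object of class `"confusion_matrix"`: a 5x5 integer matrix
#'   with stage dimnames.
#' @export
confusion_matrix <- function(true, predicted) {
  if (length(true) != length(predicted) || length(true) == 0L) {
    stop("true and predicted must have equal positive length")
  }
  lv <- stage_levels()
  m <- table(factor(true, levels = lv), factor(predicted, levels = lv))
  m <- matrix(as.integer(m), 5L, 5L, dimnames = list(true = lv,
                                                     predicted = lv))
  structure(m, class = "confusion_matrix")
}

#' Coerce a plain matrix of counts to a `confusion_matrix`
#' @param m 5x5 nonnegative numeric matrix (rows = true, cols = predicted).
#' @return A `confusion_matrix`.
#' @export
as_confusion_matrix <- function(m) {
  m <- as.matrix(m)
  if (!all(dim(m) == c(5L, 5L))) stop("confusion matrix must be 5x5")
  if (any(m < 0) || any(m != round(m))) {
    stop("confusion matrix entries must be nonnegative integers")
  }
  lv <- stage_levels()
  m <- matrix(as.integer(m), 5L, 5L, dimnames = list(true = lv,
                                                     predicted = lv))
  structure(m, class = "confusion_matrix")
}

#' @export
print.confusion_matrix <- function(x, ...) {
  cat("confusion matrix (rows = true, cols = predicted):\n")
  print(unclass(x))
  invisible(x)
}

#' Per-class precision, recall and F1 (percent)
#'
#' `TP_c` is the diagonal entry, `FP_c` the rest of column `c`, `FN_c` the
#' rest of row `c`. A class absent from both the rows and the columns has
#' no defined metrics and yields `NA` (never a silent zero).
#'
#' @param cm a `confusion_matrix`.
#' @return data.frame with columns `stage`, `PR`, `RE`, `F1`
#'   (full-precision percentages).
#' @export
per_class_metrics <- function(cm) {
  m <- unclass(cm)
  tp <- diag(m)
  fp <- colSums(m) - tp
  fn <- rowSums(m) - tp
  pr <- ifelse(tp + fp > 0, tp / (tp + fp), NA_real_)
  re <- ifelse(tp + fn > 0, tp / (tp + fn), NA_real_)
  f1 <- ifelse(!is.na(pr) & !is.na(re) & (pr + re) > 0,
               2 * pr * re / (pr + re), NA_real_)
  empty <- (rowSums(m) == 0) & (colSums(m) == 0)
  pr[empty] <- re[empty] <- f1[empty] <- NA_real_
  data.frame(stage = stage_levels(), PR = 100 * pr, RE = 100 * re,
             F1 = 100 * f1, row.names = NULL, stringsAsFactors = FALSE)
}

#' Overall accuracy, macro-F1 and Cohen's kappa
#'
#' Accuracy is the trace over the total; macro-F1 the unweighted mean of
#' the five full-precision per-class F1 values; kappa corrects accuracy by
#' the chance agreement `Pe = sum_c (row_c/N)(col_c/N)` of the marginals.
#'
#' @param cm a `confusion_matrix`.
#' @return List with `ACC` (percent), `MF1` (percent), `kappa` (unitless;
#'   `NA` when `Pe == 1`).
#' @export
overall_metrics <- function(cm) {
  m <- unclass(cm)
  N <- sum(m)
  if (N < 1) stop("empty confusion matrix")
  acc <- sum(diag(m)) / N
  pc <- per_class_metrics(cm)
  mf1 <- mean(pc$F1)
  pe <- sum((colSums(m) / N) * (rowSums(m) / N))
  kappa <- if (abs(1 - pe) < 1e-12) NA_real_ else (acc - pe) / (1 - pe)
  list(ACC = 100 * acc, MF1 = mf1, kappa = kappa)
}

#' Full metrics report for a confusion matrix
#'
#' Per-class and overall metrics at full precision plus the 1-decimal
#' half-up rounding used for presentation, together with the matrix itself.
#'
#' @param cm a `confusion_matrix`.
#' @return An object of class `"metrics_report"`.
#' @export
metrics_report <- function(cm) {
  pc <- per_class_metrics(cm)
  om <- overall_metrics(cm)
  pc_r <- pc
  pc_r[, c("PR", "RE", "F1")] <- round_half_up(pc[, c("PR", "RE", "F1")], 1)
  structure(list(confusion = cm, per_class = pc, per_class_rounded = pc_r,
                 overall = om,
                 overall_rounded = list(ACC = round_half_up(om$ACC, 1),
                                        MF1 = round_half_up(om$MF1, 1),
                                        kappa = round_half_up(om$kappa, 2))),
            class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  print(x$confusion)
  cat("\nper-class metrics (%):\n")
  print(x$per_class_rounded, row.names = FALSE)
  cat(sprintf("\noverall: ACC %.1f%%  MF1 %.1f%%  kappa %.2f\n",
              x$overall_rounded$ACC, x$overall_rounded$MF1,
              x$overall_rounded$kappa))
  invisible(x)
}

#' Serialize a metrics report to JSON
#' @param report a `metrics_report`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_metrics_json <- function(report, path) {
  jsonlite::write_json(
    list(confusion = unclass(report$confusion),
         per_class = report$per_class, overall = report$overall),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
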