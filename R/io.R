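# File formats: versioned epoch container, hypnogram and confusion-matrix
# CSVs, YAML training configs, and line-structured run logs.

#' Write a cohort to the versioned epoch container
#'
#' The container stores samples, stage codes (W/N1/N2/N3/REM), subject ids,
#' epoch indices and the sampling rate, with an embedded format version;
#' reading a mismatched version is an explicit error.
#'
#' @param es an `epoch_set`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(es, path) {
  stopifnot(inherits(es, "epoch_set"))
  saveRDS(list(format = "sleepsiam-epochs", version = 1L, fs = es$fs,
               x = es$x, stage = es$stage, subject_id = es$subject_id,
               epoch_index = es$epoch_index),
          path)
  invisible(path)
}

#' Read a cohort from the epoch container
#' @param path file written by [write_cohort()].
#' @return An `epoch_set`.
#' @export
read_cohort <- function(path) {
  obj <- tryCatch(readRDS(path),
                  error = function(e) stop("cannot parse epoch container ",
                                           path, ": ", conditionMessage(e)))
  if (!identical(obj$format, "sleepsiam-epochs")) {
    stop("not a sleepsiam epoch container: ", path)
  }
  if (!identical(obj$version, 1L)) {
    stop("unsupported epoch container version ", obj$version,
         " (this build reads version 1)")
  }
  epoch_set(obj$x, obj$stage, obj$subject_id, obj$epoch_index, obj$fs)
}

#' Write a hypnogram as CSV
#'
#' Schema: `epoch_index` (0-based, 30-s epochs), `stage` (stage code).
#'
#' @param hyp a `hypnogram`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_hypnogram_csv <- function(hyp, path) {
  stopifnot(inherits(hyp, "hypnogram"))
  utils::write.csv(data.frame(epoch_index = seq_along(hyp) - 1L,
                              stage = unclass(hyp)),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a hypnogram CSV
#' @param path file with columns `epoch_index`, `stage`.
#' @param subject_id subject id to attach.
#' @return A `hypnogram`.
#' @export
read_hypnogram_csv <- function(path, subject_id = "s1") {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("epoch_index", "stage") %in% names(df))) {
    stop("hypnogram CSV needs columns epoch_index, stage")
  }
  hypnogram(df$stage[order(df$epoch_index)], subject_id)
}

#' Read a 5x5 confusion matrix from CSV
#'
#' Accepts a plain 5x5 table of counts (rows = true stage, columns =
#' predicted stage, in W/N1/N2/N3/REM order), with or without a header row
#' of stage names; this lets published confusion tables be fed straight
#' into the metrics functions.
#'
#' @param path CSV file path.
#' @return A `confusion_matrix`.
#' @export
read_confusion_csv <- function(path) {
  first <- utils::read.csv(path, header = FALSE, nrows = 1,
                           stringsAsFactors = FALSE)
  has_header <- any(is.na(suppressWarnings(as.numeric(first[1, ]))))
  df <- utils::read.csv(path, header = has_header,
                        stringsAsFactors = FALSE)
  if (!is.numeric(df[[1]])) df <- df[, -1, drop = FALSE]  # row-name column
  as_confusion_matrix(as.matrix(df))
}

#' Write a confusion matrix as CSV
#' @param cm a `confusion_matrix`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_confusion_csv <- function(cm, path) {
  utils::write.csv(as.data.frame(unclass(cm)), path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

#' Write a training configuration as YAML
#' @param config a `train_config`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_train_config <- function(config, path) {
  stopifnot(inherits(config, "train_config"))
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' Read a training configuration from YAML
#' @param path YAML file with `train_config` fields (must include
#'   `profile`).
#' @return A `train_config`.
#' @export
read_train_config <- function(path) {
  v <- yaml::read_yaml(path)
  profile <- if (is.null(v$profile)) "paper" else v$profile
  v$profile <- NULL
  do.call(train_config, c(list(profile = profile), v))
}

#' Append a structured record to a run log
#'
#' Line-delimited JSON; every record carries a timestamp, the config hash
#' and seed, and the package version, so runs are auditable. Logs are
#' append-only.
#'
#' @param path log file path.
#' @param event short event name.
#' @param config a `train_config` (optional, adds hash + seed).
#' @param ... further named fields.
#' @return `path`, invisibly.
#' @export
log_event <- function(path, event, config = NULL, ...) {
  rec <- list(time = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"),
              event = event,
              version = as.character(utils::packageVersion("sleepsiam")),
              ...)
  if (!is.null(config)) {
    rec$config_hash <- config_hash(unclass(config))
    rec$seed <- config$rng_seed
  }
  con <- file(path, open = "a")
  on.exit(close(con))
  writeLines(jsonlite::toJSON(rec, auto_unbox = TRUE), con)
  invisible(path)
}
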