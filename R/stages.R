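#' Sleep stage codes
#'
#' The five AASM sleep stages used throughout the package, in the fixed
#' internal order W, N1, N2, N3, REM (indices 0-4). This order also fixes the
#' row/column order of every confusion matrix the package produces.
#'
#' @return Character vector of the five stage codes.
#' @export
#' @examples
#' stage_levels()
stage_levels <- function() c("W", "N1", "N2", "N3", "REM")

#' Integer index (0-based) of a stage code
#'
#' @param stage character vector of stage codes.
#' @return Integer vector, W=0, N1=1, N2=2, N3=3, REM=4.
#' @export
stage_index <- function(stage) {
  idx <- match(stage, stage_levels())
  if (anyNA(idx)) {
    stop("unknown sleep stage code(s): ",
         paste(unique(stage[is.na(idx)]), collapse = ", "))
  }
  idx - 1L
}

#' Stage code for a 0-based index
#'
#' @param index integer vector in 0..4.
#' @return Character vector of stage codes.
#' @export
stage_from_index <- function(index) {
  if (any(index < 0L | index > 4L)) stop("stage index must be in 0..4")
  stage_levels()[index + 1L]
}

#' Sentinel value for epochs excluded from scoring
#'
#' MOVEMENT and UNKNOWN annotations are not scored; they map to this
#' sentinel rather than to a stage.
#'
#' @return The string `"EXCLUDED"`.
#' @export
stage_excluded <- function() "EXCLUDED"

#' Harmonize an R&K / AASM annotation label to the five-stage scheme
#'
#' Maps raw hypnogram annotation strings onto the internal five-class scheme:
#' the deep-sleep grades S3 and S4 are merged into N3, S1/S2 map to N1/N2,
#' and MOVEMENT/UNKNOWN map to the excluded sentinel (see [stage_excluded()]).
#'
#' @param label character vector of raw annotation strings
#'   (`"W"`, `"S1"`..`"S4"`, `"N1"`..`"N3"`, `"REM"`/`"R"`,
#'   `"MOVEMENT"`, `"UNKNOWN"`, `"?"`).
#' @return Character vector of stage codes or the excluded sentinel.
#' @export
#' @examples
#' stage_from_rk_label(c("S4", "S3", "W", "MOVEMENT"))
stage_from_rk_label <- function(label) {
  map <- c(W = "W", S1 = "N1", S2 = "N2", S3 = "N3", S4 = "N3",
           N1 = "N1", N2 = "N2", N3 = "N3", N4 = "N3",
           REM = "REM", R = "REM",
           MOVEMENT = stage_excluded(), UNKNOWN = stage_excluded(),
           "?" = stage_excluded())
  out <- unname(map[toupper(trimws(label))])
  if (anyNA(out)) {
    bad <- unique(label[is.na(out)])
    stop("unrecognized sleep annotation label(s): ",
         paste(bad, collapse = ", "))
  }
  out
}
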