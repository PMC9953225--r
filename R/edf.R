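# Minimal EDF (European Data Format) adapter: 16-bit signals, 1-second data
# records. Supports reading one channel of an EDF/EDF+ file and writing
# simple single- or multi-channel EDFs (used for round-trip testing and for
# feeding real PSG recordings into the pipeline). Epoching into 30-s
# windows is done downstream by the preprocessing step.

pad_ascii <- function(s, width) {
  s <- substr(as.character(s), 1L, width)
  sprintf("%-*s", width, s)
}

#' Write signals to an EDF file
#'
#' Each channel is scaled to the full 16-bit digital range against its own
#' physical min/max. All channels must share one sampling rate; record
#' duration is 1 s.
#'
#' @param path output file path.
#' @param signals named list of numeric vectors (equal lengths, a whole
#'   number of seconds at `fs`).
#' @param fs sampling rate in Hz.
#' @param phys_dim physical dimension label (default `"uV"`).
#' @return `path`, invisibly.
#' @export
write_edf <- function(path, signals, fs, phys_dim = "uV") {
  if (is.null(names(signals)) || any(names(signals) == "")) {
    stop("signals must be a named list of channels")
  }
  ns <- length(signals)
  len <- unique(vapply(signals, length, integer(1)))
  if (length(len) != 1L) stop("all channels must have equal length")
  if (len %% fs != 0) stop("signal length must be a whole number of seconds")
  n_rec <- len / fs
  con <- file(path, open = "wb")
  on.exit(close(con))
  hdr_bytes <- 256L + 256L * ns
  writeChar(paste0(pad_ascii("0", 8), pad_ascii("synthetic", 80),
                   pad_ascii("sleepsiam", 80), "01.01.00", "00.00.00",
                   pad_ascii(hdr_bytes, 8), pad_ascii("", 44),
                   pad_ascii(n_rec, 8), pad_ascii(1, 8), pad_ascii(ns, 4)),
            con, eos = NULL)
  pmin <- vapply(signals, function(s) min(s) - 1e-9, numeric(1))
  pmax <- vapply(signals, function(s) max(s) + 1e-9, numeric(1))
  field <- function(vals, width) {
    paste(vapply(vals, pad_ascii, character(1), width = width),
          collapse = "")
  }
  writeChar(paste0(field(names(signals), 16), field(rep("", ns), 80),
                   field(rep(phys_dim, ns), 8),
                   field(sprintf("%.8g", pmin), 8),
                   field(sprintf("%.8g", pmax), 8),
                   field(rep(-32768L, ns), 8), field(rep(32767L, ns), 8),
                   field(rep("", ns), 80), field(rep(fs, ns), 8),
                   field(rep("", ns), 32)),
            con, eos = NULL)
  dig <- lapply(seq_len(ns), function(i) {
    as.integer(round((signals[[i]] - pmin[i]) / (pmax[i] - pmin[i]) * 65535 -
                       32768))
  })
  for (r in seq_len(n_rec)) {
    idx <- ((r - 1L) * fs + 1L):(r * fs)
    for (i in seq_len(ns)) writeBin(dig[[i]][idx], con, size = 2L,
                                    endian = "little")
  }
  invisible(path)
}

#' Read one channel from an EDF/EDF+ file
#'
#' @param path EDF file path.
#' @param channel_name label of the channel to extract (whitespace-trimmed
#'   match).
#' @return List with `samples` (numeric, physical units), `fs` (Hz) and
#'   `channel` (the matched label).
#' @export
read_edf <- function(path, channel_name) {
  con <- file(path, open = "rb")
  on.exit(close(con))
  rd <- function(n) {
    x <- readChar(con, n, useBytes = TRUE)
    if (length(x) == 0L || nchar(x, type = "bytes") < n) {
      stop("truncated EDF file: ", path)
    }
    x
  }
  rd(8)                       # version
  rd(80); rd(80); rd(8); rd(8)
  rd(8)                       # header bytes
  rd(44)
  n_rec <- as.integer(rd(8))
  duration <- as.numeric(rd(8))
  ns <- as.integer(rd(4))
  if (is.na(ns) || ns < 1L) stop("invalid EDF header: ", path)
  labels <- trimws(vapply(seq_len(ns), function(i) rd(16), character(1)))
  for (i in seq_len(ns)) rd(80)            # transducer
  for (i in seq_len(ns)) rd(8)             # phys dim
  pmin <- as.numeric(vapply(seq_len(ns), function(i) rd(8), character(1)))
  pmax <- as.numeric(vapply(seq_len(ns), function(i) rd(8), character(1)))
  dmin <- as.numeric(vapply(seq_len(ns), function(i) rd(8), character(1)))
  dmax <- as.numeric(vapply(seq_len(ns), function(i) rd(8), character(1)))
  for (i in seq_len(ns)) rd(80)            # prefilter
  nsamp <- as.integer(vapply(seq_len(ns), function(i) rd(8), character(1)))
  for (i in seq_len(ns)) rd(32)
  ch <- which(labels == trimws(channel_name))
  if (length(ch) != 1L) {
    stop("channel '", channel_name, "' not found; available channels: ",
         paste(labels, collapse = ", "))
  }
  out <- numeric(n_rec * nsamp[ch])
  pos <- 0L
  for (r in seq_len(n_rec)) {
    for (i in seq_len(ns)) {
      v <- readBin(con, "integer", n = nsamp[i], size = 2L, signed = TRUE,
                   endian = "little")
      if (length(v) < nsamp[i]) stop("truncated EDF data in ", path)
      if (i == ch) {
        out[pos + seq_along(v)] <- v
        pos <- pos + length(v)
      }
    }
  }
  scale <- (pmax[ch] - pmin[ch]) / (dmax[ch] - dmin[ch])
  list(samples = (out - dmin[ch]) * scale + pmin[ch],
       fs = nsamp[ch] / duration, channel = labels[ch])
}
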