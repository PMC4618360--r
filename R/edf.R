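# Minimal EDF (European Data Format) reader and writer.
#
# Supports plain EDF with equal sampling rate across signals, which is what
# multichannel EEG amplifiers produce. Samples are stored as 16-bit
# little-endian integers scaled between per-signal physical and digital
# ranges, so a write/read round trip is exact up to one quantization step
# (physical range / 65535).

.edf_pad <- function(x, width) {
  x <- as.character(x)
  if (nchar(x) > width)
    stop(sprintf("EDF header field too long ('%s' > %d chars)", x, width),
         call. = FALSE)
  formatC(x, width = -width)  # left-justified, space padded
}

# shortest representation of a number that fits the 8-char EDF numeric field
.edf_num <- function(x) {
  for (digits in 7:0) {
    s <- formatC(x, format = "fg", digits = digits, width = 1)
    if (nchar(s) <= 8L) return(s)
  }
  stop("cannot represent ", x, " in an 8-character EDF field", call. = FALSE)
}

#' Write a continuous recording to an EDF file
#'
#' @param rec A [recording()] (or a [trial_set()], whose trials are
#'   concatenated in order before writing).
#' @param path Output path.
#' @param record_s Data-record duration in seconds; the total duration must
#'   not be shorter than one record. A trailing partial record is dropped
#'   with a warning.
#' @return `path`, invisibly.
#' @seealso [read_edf()]
#' @export
write_edf <- function(rec, path, record_s = 1) {
  if (is_trial_set(rec)) {
    d <- dim(rec$data)
    rec <- recording(matrix(aperm(rec$data, c(2L, 3L, 1L)), nrow = d[2L]),
                     rec$rate, rec$channel_names)
  }
  stopifnot(inherits(rec, "Recording"))
  spr <- record_s * rec$rate
  if (spr != round(spr) || spr < 1)
    stop("`record_s` times the sampling rate must be a positive integer",
         call. = FALSE)
  spr <- as.integer(spr)
  nrec <- ncol(rec$data) %/% spr
  if (nrec < 1L)
    stop("recording shorter than one data record", call. = FALSE)
  if (nrec * spr < ncol(rec$data))
    warning(sprintf("dropping %d trailing samples (partial EDF record)",
                    ncol(rec$data) - nrec * spr))
  nch <- nrow(rec$data)
  x <- rec$data[, seq_len(nrec * spr), drop = FALSE]

  pmin_ <- apply(x, 1L, min)
  pmax_ <- apply(x, 1L, max)
  flat <- pmax_ - pmin_ < .Machine$double.eps
  pmin_[flat] <- pmin_[flat] - 1
  pmax_[flat] <- pmax_[flat] + 1
  dmin <- -32768L; dmax <- 32767L
  dig <- round(sweep(sweep(x, 1L, pmin_), 1L, (pmax_ - pmin_) / (dmax - dmin), "/")) + dmin

  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- paste0(.edf_pad("0", 8), .edf_pad("X X X X", 80),
                .edf_pad("Startdate 01-JAN-2000 X X X", 80),
                .edf_pad("01.01.00", 8), .edf_pad("00.00.00", 8),
                .edf_pad(256L * (1L + nch), 8), .edf_pad("", 44),
                .edf_pad(nrec, 8), .edf_pad(.edf_num(record_s), 8),
                .edf_pad(nch, 4))
  sig <- paste0(
    paste(vapply(rec$channel_names, function(s) .edf_pad(paste("EEG", s), 16), ""), collapse = ""),
    paste(rep(.edf_pad("", 80), nch), collapse = ""),
    paste(rep(.edf_pad("uV", 8), nch), collapse = ""),
    paste(vapply(pmin_, function(v) .edf_pad(.edf_num(v), 8), ""), collapse = ""),
    paste(vapply(pmax_, function(v) .edf_pad(.edf_num(v), 8), ""), collapse = ""),
    paste(rep(.edf_pad(dmin, 8), nch), collapse = ""),
    paste(rep(.edf_pad(dmax, 8), nch), collapse = ""),
    paste(rep(.edf_pad("", 80), nch), collapse = ""),
    paste(rep(.edf_pad(spr, 8), nch), collapse = ""),
    paste(rep(.edf_pad("", 32), nch), collapse = ""))
  writeChar(paste0(hdr, sig), con, eos = NULL)
  for (r in seq_len(nrec)) {
    block <- dig[, ((r - 1L) * spr + 1L):(r * spr), drop = FALSE]
    writeBin(as.integer(t(block)), con, size = 2L, endian = "little")
  }
  invisible(path)
}

#' Read an EDF file as a continuous recording
#'
#' Reads plain EDF/EDF+ files whose signals all share one sampling rate
#' (mixed per-signal rates raise a format error). Annotation channels are
#' not interpreted. The result is continuous; epoch it with
#' [epoch_recording()] before feature extraction.
#'
#' @param path Path to an EDF file.
#' @return A [recording()].
#' @export
read_edf <- function(path) {
  if (!file.exists(path)) stop("EDF file not found: ", path, call. = FALSE)
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(n) readChar(con, n, useBytes = TRUE)
  num <- function(s) {
    v <- suppressWarnings(as.numeric(trimws(s)))
    if (is.na(v)) stop("malformed EDF header field in ", path, call. = FALSE)
    v
  }
  rd(8 + 80 + 80 + 8 + 8)                    # version, ids, date, time
  header_bytes <- num(rd(8))
  rd(44)
  nrec <- num(rd(8))
  record_s <- num(rd(8))
  nch <- num(rd(4))
  if (nch < 1) stop("EDF format error: file declares 0 signals: ", path,
                    call. = FALSE)
  labels <- vapply(seq_len(nch), function(i) trimws(rd(16)), "")
  rd(80 * nch); rd(8 * nch)                  # transducer, physical dimension
  pmin_ <- vapply(seq_len(nch), function(i) num(rd(8)), 0)
  pmax_ <- vapply(seq_len(nch), function(i) num(rd(8)), 0)
  dmin  <- vapply(seq_len(nch), function(i) num(rd(8)), 0)
  dmax  <- vapply(seq_len(nch), function(i) num(rd(8)), 0)
  rd(80 * nch)                               # prefiltering
  spr <- vapply(seq_len(nch), function(i) num(rd(8)), 0)
  rd(32 * nch)
  if (length(unique(spr)) != 1L)
    stop("EDF format error: signals have inconsistent sampling rates: ", path,
         call. = FALSE)
  if (header_bytes != 256 * (1 + nch))
    stop("EDF format error: header length mismatch: ", path, call. = FALSE)
  spr <- spr[1L]
  rate <- spr / record_s
  out <- matrix(0, nch, nrec * spr)
  for (r in seq_len(nrec)) {
    raw <- readBin(con, "integer", n = nch * spr, size = 2L, signed = TRUE,
                   endian = "little")
    if (length(raw) < nch * spr)
      stop("EDF format error: truncated data record in ", path, call. = FALSE)
    out[, ((r - 1) * spr + 1):(r * spr)] <- matrix(raw, nrow = spr)[, seq_len(nch)] |> t()
  }
  phys <- sweep(sweep(out, 1L, (pmax_ - pmin_) / (dmax - dmin), "*"),
                1L, pmin_ - dmin * (pmax_ - pmin_) / (dmax - dmin), "+")
  ch <- sub("^EEG ", "", labels)
  if (anyDuplicated(ch)) ch <- make.unique(ch)
  recording(phys, rate, ch)
}
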