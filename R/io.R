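#' Write a recording to EDF with a JSON marker sidecar
#'
#' Minimal European Data Format writer: one data record per second, 16-bit
#' samples, physical dimension microvolts, per-channel physical scaling from
#' the data range.  Event markers are written to a sidecar JSON file (an
#' array of `{onset_s, label}` objects) rather than an EDF annotations
#' stream.  The trailing partial second of the recording is zero-padded in
#' the file; the true sample count is restored on read via the sidecar.
#'
#' @param rec An `mi_recording`.
#' @param path Output `.edf` path.
#' @param markers_path Sidecar JSON path; default `<path>.markers.json`.
#' @return `path`, invisibly.
#' @export
write_edf <- function(rec, path, markers_path = paste0(path, ".markers.json")) {
  stopifnot(inherits(rec, "mi_recording"))
  ns <- nrow(rec$data); n <- ncol(rec$data)
  spr <- as.integer(round(rec$fs))              # samples per 1 s record
  if (abs(spr - rec$fs) > 1e-9) stop_mibci("EDF writer requires an integer fs")
  n_rec <- as.integer(ceiling(n / spr))
  pad <- n_rec * spr - n

  pmin_ <- apply(rec$data, 1, min); pmax_ <- apply(rec$data, 1, max)
  flat <- pmax_ - pmin_ < 1e-9
  pmin_[flat] <- pmin_[flat] - 1; pmax_[flat] <- pmax_[flat] + 1

  fixed <- function(s, w) {
    s <- substr(s, 1, w)
    paste0(s, strrep(" ", w - nchar(s)))
  }
  con <- file(path, "wb"); on.exit(close(con), add = TRUE)
  writeChar(paste0(
    fixed("0", 8), fixed("X X X X", 80), fixed(rec$session_id, 80),
    fixed("01.01.26", 8), fixed("00.00.00", 8),
    fixed(as.character(256 * (ns + 1)), 8), fixed("EDF", 44),
    fixed(as.character(n_rec), 8), fixed("1", 8), fixed(as.character(ns), 4)
  ), con, eos = NULL)
  field <- function(vals, w) writeChar(paste(vapply(vals, fixed, "", w = w),
                                             collapse = ""), con, eos = NULL)
  field(rec$channel_names, 16)
  field(rep("EEG", ns), 80)
  field(rep("uV", ns), 8)
  field(formatC(pmin_, format = "g", digits = 7), 8)
  field(formatC(pmax_, format = "g", digits = 7), 8)
  field(rep("-32768", ns), 8)
  field(rep("32767", ns), 8)
  field(rep("", ns), 80)
  field(rep(as.character(spr), ns), 8)
  field(rep("", ns), 32)

  scale <- (pmax_ - pmin_) / 65535
  padded <- cbind(rec$data, matrix(rep(pmin_, pad), ns, pad))
  for (r in seq_len(n_rec)) {
    cols <- ((r - 1) * spr + 1):(r * spr)
    dig <- round((padded[, cols, drop = FALSE] - pmin_) / scale) - 32768
    writeBin(as.integer(t(dig)), con, size = 2, endian = "little")
  }

  jsonlite::write_json(
    list(n_samples = n, fs = rec$fs, session_id = rec$session_id,
         markers = rec$markers),
    markers_path, auto_unbox = TRUE, digits = NA, dataframe = "rows")
  invisible(path)
}

#' Read an EDF recording written by [write_edf()]
#'
#' @param path `.edf` path.
#' @param markers_path Sidecar JSON path; default `<path>.markers.json`.
#' @return An `mi_recording` (quantized to the 16-bit EDF resolution).
#' @export
read_edf <- function(path, markers_path = paste0(path, ".markers.json")) {
  con <- file(path, "rb"); on.exit(close(con), add = TRUE)
  hdr <- readChar(con, 256, useBytes = TRUE)
  n_rec <- as.integer(substr(hdr, 237, 244))
  ns <- as.integer(substr(hdr, 253, 256))
  sig <- readChar(con, 256 * ns, useBytes = TRUE)
  fld <- function(offset, w) {
    start <- offset * ns
    vapply(seq_len(ns), function(i)
      trimws(substr(sig, start + (i - 1) * w + 1, start + i * w)), "")
  }
  labels <- fld(0, 16)
  pmin_ <- as.numeric(fld(104, 8))
  pmax_ <- as.numeric(fld(112, 8))
  spr <- as.integer(fld(216, 8))[1]
  scale <- (pmax_ - pmin_) / 65535

  raw <- readBin(con, integer(), n = n_rec * ns * spr, size = 2,
                 endian = "little")
  data <- matrix(0, ns, n_rec * spr)
  for (r in seq_len(n_rec)) {
    block <- matrix(raw[((r - 1) * ns * spr + 1):(r * ns * spr)],
                    nrow = spr, ncol = ns)
    data[, ((r - 1) * spr + 1):(r * spr)] <- t(block)
  }
  data <- (data + 32768) * scale + pmin_

  side <- jsonlite::read_json(markers_path, simplifyVector = TRUE)
  n <- side$n_samples
  markers <- if (length(side$markers)) {
    data.frame(onset = as.numeric(side$markers$onset),
               label = as.character(side$markers$label),
               stringsAsFactors = FALSE)
  } else {
    data.frame(onset = numeric(0), label = character(0))
  }
  raw_recording(data[, seq_len(n), drop = FALSE], side$fs, labels, markers,
                side$session_id %||% "S1")
}
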