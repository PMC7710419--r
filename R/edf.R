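#' Write a recording to a European Data Format (EDF) file
#'
#' Minimal EDF writer: one data record per second, 16-bit little-endian
#' samples, physical unit microvolts, symmetric physical range covering the
#' data. The recording duration must be an integer number of seconds.
#'
#' Optionally writes a JSON sidecar (`<file>.json`) holding the recording's
#' annotations (`label`, `onset_s`, `offset_s`) and any extra ground-truth
#' metadata, which [read_edf()] picks up again.
#'
#' @param recording A [new_recording()] object.
#' @param path Output file path (conventionally `.edf`).
#' @param sidecar Logical; write the JSON annotation sidecar (default TRUE
#'   when there are annotations or `extra` is non-empty).
#' @param extra Named list of additional metadata for the sidecar (e.g.
#'   planted ground truth from the synthetic generator).
#' @return `path`, invisibly.
#' @export
write_edf <- function(recording, path, sidecar = NULL, extra = list()) {
  data <- recording$data
  fs <- recording$fs
  ns <- nrow(data)
  if (fs != round(fs)) stop("EDF writer requires an integer sampling rate")
  n_rec <- ncol(data) / fs
  if (n_rec != round(n_rec)) {
    stop("EDF writer requires an integer number of seconds of data")
  }
  n_rec <- as.integer(round(n_rec))

  phys_max <- max(1, ceiling(max(abs(data))))
  phys_min <- -phys_max
  dig_max <- 32767L
  dig_min <- -32767L
  # physical = digital * scale; symmetric ranges make the mapping a pure gain
  scale <- phys_max / dig_max
  dig <- matrix(as.integer(round(data / scale)), nrow = ns)
  dig[dig > dig_max] <- dig_max
  dig[dig < dig_min] <- dig_min

  pad <- function(x, width) {
    x <- substr(as.character(x), 1L, width)
    formatC(x, width = width, flag = "-")
  }
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar(paste0(
    pad("0", 8), pad("X X X X", 80), pad(recording$id, 80),
    pad("01.01.01", 8), pad("00.00.00", 8),
    pad(256L + 256L * ns, 8), pad("", 44), pad(n_rec, 8), pad("1", 8),
    pad(ns, 4),
    paste(pad(recording$channel_labels, 16), collapse = ""),
    paste(rep(pad("", 80), ns), collapse = ""),
    paste(rep(pad("uV", 8), ns), collapse = ""),
    paste(rep(pad(phys_min, 8), ns), collapse = ""),
    paste(rep(pad(phys_max, 8), ns), collapse = ""),
    paste(rep(pad(dig_min, 8), ns), collapse = ""),
    paste(rep(pad(dig_max, 8), ns), collapse = ""),
    paste(rep(pad("", 80), ns), collapse = ""),
    paste(rep(pad(as.integer(fs), 8), ns), collapse = ""),
    paste(rep(pad("", 32), ns), collapse = "")
  ), con, eos = NULL)
  for (r in seq_len(n_rec)) {
    cols <- ((r - 1L) * fs + 1L):(r * fs)
    # EDF stores each signal's samples contiguously within a record
    writeBin(as.integer(t(dig[, cols, drop = FALSE])), con,
             size = 2L, endian = "little")
  }

  if (is.null(sidecar)) sidecar <- nrow(recording$annotations) > 0 || length(extra) > 0
  if (sidecar) {
    meta <- c(list(id = recording$id,
                   annotations = recording$annotations), extra)
    jsonlite::write_json(meta, paste0(path, ".json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  invisible(path)
}

#' Read an EDF file into a recording
#'
#' Reads continuous EDF (16-bit samples). All signals must share one
#' sampling rate. If `<file>.json` exists, its `annotations` table is
#' attached to the recording.
#'
#' @param path Path to an EDF file.
#' @return A [new_recording()] object (data in the file's physical units).
#' @export
read_edf <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  rd_str <- function(width) trimws(readChar(con, width, useBytes = TRUE))
  rd_num <- function(width) as.numeric(rd_str(width))
  rd_str(8)                      # version
  rd_str(80)                     # patient id
  id <- rd_str(80)
  rd_str(8); rd_str(8)           # start date, time
  rd_num(8)                      # header bytes
  rd_str(44)
  n_rec <- rd_num(8)
  rec_dur <- rd_num(8)
  ns <- as.integer(rd_num(4))

  labels <- vapply(seq_len(ns), function(i) rd_str(16), character(1))
  for (i in seq_len(ns)) rd_str(80)          # transducer
  for (i in seq_len(ns)) rd_str(8)           # physical dimension
  phys_min <- vapply(seq_len(ns), function(i) rd_num(8), numeric(1))
  phys_max <- vapply(seq_len(ns), function(i) rd_num(8), numeric(1))
  dig_min <- vapply(seq_len(ns), function(i) rd_num(8), numeric(1))
  dig_max <- vapply(seq_len(ns), function(i) rd_num(8), numeric(1))
  for (i in seq_len(ns)) rd_str(80)          # prefiltering
  spr <- vapply(seq_len(ns), function(i) rd_num(8), numeric(1))
  for (i in seq_len(ns)) rd_str(32)
  if (length(unique(spr)) != 1L) stop("mixed sampling rates are not supported")
  fs <- spr[1] / rec_dur

  gain <- (phys_max - phys_min) / (dig_max - dig_min)
  offset <- phys_min - gain * dig_min
  data <- matrix(0, nrow = ns, ncol = n_rec * spr[1])
  for (r in seq_len(n_rec)) {
    raw <- readBin(con, integer(), n = ns * spr[1], size = 2L,
                   endian = "little", signed = TRUE)
    block <- matrix(raw, nrow = spr[1], ncol = ns)   # sample-major per signal
    cols <- ((r - 1L) * spr[1] + 1L):(r * spr[1])
    data[, cols] <- t(block) * gain + offset
  }

  ann <- NULL
  sc <- paste0(path, ".json")
  if (file.exists(sc)) {
    meta <- jsonlite::read_json(sc, simplifyVector = TRUE)
    if (!is.null(meta$annotations) && length(meta$annotations)) {
      ann <- as.data.frame(meta$annotations)
    }
  }
  new_recording(data, fs, channel_labels = labels, annotations = ann, id = id)
}
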