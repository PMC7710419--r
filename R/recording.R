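#' Standard 16-channel 10-20 montage labels
#'
#' Channel order used throughout: Fp1, Fp2, F3, F4, F7, F8, C3, C4, P3, P4,
#' O1, O2, T3, T4, T5, T6.
#'
#' @return Character vector of 16 channel labels.
#' @export
montage_16 <- function() {
  c("Fp1", "Fp2", "F3", "F4", "F7", "F8", "C3", "C4",
    "P3", "P4", "O1", "O2", "T3", "T4", "T5", "T6")
}

#' Construct a multichannel EEG recording
#'
#' A `recording` holds continuous multichannel EEG as a channels x samples
#' matrix in microvolts, with sampling rate, unique channel labels and
#' optional annotations (e.g. seizure onset/offset marks).
#'
#' @param data Numeric matrix, channels x samples, in microvolts. No NaN/NA.
#' @param fs Sampling rate in Hz (> 0).
#' @param channel_labels Character vector of unique labels, one per row of
#'   `data`. Defaults to [montage_16()] when there are 16 channels.
#' @param annotations Data frame with columns `label`, `onset_s`, `offset_s`
#'   (may be empty).
#' @param id Free-form recording identifier used for provenance.
#'
#' @return An object of class `recording`.
#' @export
new_recording <- function(data, fs, channel_labels = NULL,
                          annotations = NULL, id = "recording") {
  data <- as.matrix(data)
  if (!is.numeric(data) || anyNA(data) || any(!is.finite(data))) {
    stop("recording data must be a finite numeric matrix (microvolts)")
  }
  if (!is.numeric(fs) || length(fs) != 1L || fs <= 0) {
    stop("fs must be a single positive sampling rate in Hz")
  }
  if (is.null(channel_labels)) {
    channel_labels <- if (nrow(data) == 16L) montage_16() else
      paste0("ch", seq_len(nrow(data)))
  }
  if (length(channel_labels) != nrow(data) || anyDuplicated(channel_labels)) {
    stop("channel_labels must be unique and match the number of data rows")
  }
  if (is.null(annotations)) {
    annotations <- data.frame(label = character(), onset_s = numeric(),
                              offset_s = numeric())
  }
  rownames(data) <- channel_labels
  structure(
    list(data = data, fs = fs, channel_labels = channel_labels,
         annotations = annotations, id = id),
    class = "recording"
  )
}

#' @export
print.recording <- function(x, ...) {
  cat(sprintf("<recording '%s'>: %d channels x %d samples, fs = %g Hz (%.1f s)\n",
              x$id, nrow(x$data), ncol(x$data), x$fs, ncol(x$data) / x$fs))
  if (nrow(x$annotations)) {
    cat(sprintf("  %d annotation(s): %s\n", nrow(x$annotations),
                paste(x$annotations$label, collapse = ", ")))
  }
  invisible(x)
}

#' Duration of a recording in seconds
#' @param recording A [new_recording()] object.
#' @return Duration in seconds.
#' @export
recording_duration <- function(recording) {
  ncol(recording$data) / recording$fs
}

#' Construct an epoch set
#'
#' Fixed-length, artifact-screened epochs derived from a recording. The
#' `epochs` array is n_epochs x channels x samples; `retained_mask` records,
#' for every epoch of the original segmentation, whether it survived
#' artifact rejection (all epochs present before rejection).
#'
#' @param epochs Numeric array n_epochs x channels x samples (microvolts).
#' @param epoch_length Epoch length in seconds.
#' @param fs Sampling rate in Hz.
#' @param channel_labels Character vector of channel labels.
#' @param retained_mask Logical vector over the original epochs.
#' @param provenance List with source recording id, state (`"pre"`/`"post"`)
#'   and seizure index, carried through to output tables.
#'
#' @return An object of class `epoch_set`.
#' @export
new_epoch_set <- function(epochs, epoch_length, fs, channel_labels,
                          retained_mask = NULL, provenance = list()) {
  d <- dim(epochs)
  if (length(d) != 3L) stop("epochs must be a 3-d array: epochs x channels x samples")
  if (d[3] != round(epoch_length * fs)) {
    stop("samples per epoch must equal epoch_length * fs exactly")
  }
  if (is.null(retained_mask)) retained_mask <- rep(TRUE, d[1])
  structure(
    list(epochs = epochs, epoch_length = epoch_length, fs = fs,
         channel_labels = channel_labels, retained_mask = retained_mask,
         provenance = provenance),
    class = "epoch_set"
  )
}

#' @export
print.epoch_set <- function(x, ...) {
  cat(sprintf("<epoch_set>: %d epochs (%d retained of %d original) x %d channels x %d samples, %g s @ %g Hz\n",
              dim(x$epochs)[1], sum(x$retained_mask), length(x$retained_mask),
              dim(x$epochs)[2], dim(x$epochs)[3], x$epoch_length, x$fs))
  invisible(x)
}

n_epochs <- function(epochs) dim(epochs$epochs)[1]
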