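#' Re-reference a recording to the common average
#'
#' Subtracts, at every sample, the instantaneous mean across channels, so
#' the channel mean is zero at each time point. Idempotent.
#'
#' @param recording A [new_recording()] with at least 2 channels.
#' @return The re-referenced recording.
#' @export
rereference_average <- function(recording) {
  if (nrow(recording$data) < 2) {
    stop("average re-referencing needs at least 2 channels")
  }
  out <- recording
  out$data <- sweep(recording$data, 2, colMeans(recording$data), "-")
  out
}

#' Zero-phase band-pass filter a recording
#'
#' 4th-order Butterworth applied forward-backward, so the filter has zero
#' group delay and epoch alignment is preserved. Defaults to the 1-45 Hz
#' analysis band, which also removes DC drift and mains-range noise.
#'
#' The forward-backward pass is realized by applying the filter's squared
#' magnitude response in the frequency domain to odd-reflection-padded
#' signals (see [bandpass_matrix()]), which is vectorized across channels.
#'
#' @param recording A [new_recording()].
#' @param low,high Pass-band edges in Hz; `0 < low < high < fs/2`.
#' @param order Butterworth order per pass (default 4).
#' @return The filtered recording.
#' @export
bandpass <- function(recording, low = 1, high = 45, order = 4) {
  out <- recording
  out$data <- t(bandpass_matrix(t(recording$data), recording$fs, low, high,
                                order))
  rownames(out$data) <- recording$channel_labels
  out
}

#' Zero-phase Butterworth band-pass of signal columns
#'
#' Forward-backward (zero-phase) Butterworth filtering of each column:
#' columns are padded by odd reflection at both ends to suppress boundary
#' transients, transformed, multiplied by the squared magnitude response
#' `|H|^2` of the digital Butterworth band-pass (the transfer function of
#' one forward plus one backward pass), and inverse-transformed.
#'
#' @param x Numeric matrix, samples x columns.
#' @param fs Sampling rate (Hz).
#' @param low,high Pass-band edges (Hz); `0 < low < high < fs/2`.
#' @param order Butterworth order per pass (default 4).
#' @param pad_s Reflection padding per end in seconds (default 3, capped at
#'   the signal length).
#' @return Filtered matrix of the same dimensions.
#' @export
bandpass_matrix <- function(x, fs, low, high, order = 4, pad_s = 3) {
  if (!(low > 0 && high > low && high < fs / 2)) {
    stop("band edges must satisfy 0 < low < high < fs/2")
  }
  x <- as.matrix(x)
  n <- nrow(x)
  np <- min(n - 1L, as.integer(round(pad_s * fs)))
  top <- 2 * x[rep(1L, np), , drop = FALSE] - x[np + 1L - seq_len(np), , drop = FALSE]
  bot <- 2 * x[rep(n, np), , drop = FALSE] - x[n - seq_len(np), , drop = FALSE]
  y <- rbind(top, x, bot)
  ny <- nrow(y)
  bf <- signal::butter(order, c(low, high) / (fs / 2), type = "pass")
  key <- paste("bp", ny, fs, low, high, order, sep = "_")
  H2 <- .h2_cache[[key]]
  if (is.null(H2)) {
    w <- 2 * pi * (seq_len(ny) - 1) / ny
    ek <- exp(-1i * outer(w, seq_along(bf$b) - 1))
    H2 <- Mod((ek %*% bf$b) / (ek %*% bf$a))^2
    .h2_cache[[key]] <- H2
  }
  out <- Re(stats::mvfft(stats::mvfft(y) * as.vector(H2), inverse = TRUE)) / ny
  out[np + seq_len(n), , drop = FALSE]
}

#' Segment a recording into fixed-length epochs
#'
#' Cuts the recording into consecutive non-overlapping epochs of
#' `epoch_length` seconds starting at the first sample; a trailing
#' remainder shorter than one epoch is discarded.
#'
#' @param recording A [new_recording()] at least `epoch_length` s long.
#' @param epoch_length Epoch length in seconds (default 6).
#' @param provenance Optional provenance list stored on the epoch set.
#' @return A [new_epoch_set()] with all epochs retained.
#' @export
segment_epochs <- function(recording, epoch_length = 6, provenance = NULL) {
  fs <- recording$fs
  spw <- as.integer(round(epoch_length * fs))
  n_ep <- floor(ncol(recording$data) / spw)
  if (n_ep < 1) {
    stop(sprintf("recording (%.1f s) is shorter than one epoch (%g s)",
                 recording_duration(recording), epoch_length))
  }
  nch <- nrow(recording$data)
  ep <- array(0, dim = c(n_ep, nch, spw))
  for (e in seq_len(n_ep)) {
    ep[e, , ] <- recording$data[, ((e - 1L) * spw + 1L):(e * spw)]
  }
  if (is.null(provenance)) provenance <- list(id = recording$id)
  new_epoch_set(ep, epoch_length, fs, recording$channel_labels,
                provenance = provenance)
}

#' Reject epochs containing high-amplitude artifacts
#'
#' An epoch is excluded iff any sample on any channel has `|x|` strictly
#' greater than the threshold (the boundary value itself is retained;
#' set `inclusive = TRUE` to reject at `|x| >= threshold`).
#'
#' @param epochs A [new_epoch_set()].
#' @param threshold Rejection threshold in microvolts (default 80).
#' @param inclusive Reject at `>=` instead of `>` (default FALSE).
#' @return The epoch set restricted to retained epochs; `retained_mask`
#'   keeps the per-original-epoch decisions.
#' @export
reject_artifacts <- function(epochs, threshold = 80, inclusive = FALSE) {
  if (threshold <= 0) stop("threshold must be > 0")
  peak <- apply(abs(epochs$epochs), 1, max)
  keep <- if (inclusive) peak < threshold else peak <= threshold
  if (!any(keep)) {
    stop("all epochs rejected: no clean data at this threshold")
  }
  mask <- epochs$retained_mask
  mask[mask] <- keep
  out <- epochs
  out$epochs <- epochs$epochs[keep, , , drop = FALSE]
  out$retained_mask <- mask
  out
}

#' Run the full preprocessing chain on a recording
#'
#' Fixed order: average re-reference, 1-45 Hz zero-phase band-pass,
#' segmentation into 6-s epochs, amplitude-threshold artifact rejection.
#'
#' @param recording A [new_recording()].
#' @param band_low_hz,band_high_hz Filter pass-band (Hz).
#' @param epoch_s Epoch length (seconds).
#' @param reject_uv Rejection threshold (microvolts).
#' @param reject_inclusive Reject at `>=` instead of `>`.
#' @param provenance Optional provenance list (id, state, seizure index).
#' @return A [new_epoch_set()] of retained epochs.
#' @export
preprocess <- function(recording, band_low_hz = 1, band_high_hz = 45,
                       epoch_s = 6, reject_uv = 80,
                       reject_inclusive = FALSE, provenance = NULL) {
  rec <- rereference_average(recording)
  rec <- bandpass(rec, band_low_hz, band_high_hz)
  ep <- segment_epochs(rec, epoch_s, provenance = provenance)
  reject_artifacts(ep, reject_uv, reject_inclusive)
}
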