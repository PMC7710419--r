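# Pooled Welch cross-spectral array over all windows of the given epochs.
# Returns freqs, S (nf x nch x nch complex, S[f, i, j] = <X_i conj(X_j)>)
# and the number of averaging segments.
welch_cross <- function(epochs, window_s = 2, overlap = 0.5, taper = "hann",
                        epoch_subset = NULL) {
  fs <- epochs$fs
  nw <- as.integer(round(window_s * fs))
  ns <- dim(epochs$epochs)[3]
  if (nw > ns) stop("window_s must not exceed the epoch length")
  w <- taper_window(nw, taper)
  nf <- nw %/% 2 + 1L
  starts <- welch_starts(ns, nw, overlap)
  nch <- dim(epochs$epochs)[2]
  eps <- epoch_subset %||% seq_len(dim(epochs$epochs)[1])
  S <- array(0 + 0i, c(nf, nch, nch))
  nseg <- 0L
  for (e in eps) {
    for (s0 in starts) {
      seg <- matrix(epochs$epochs[e, , s0:(s0 + nw - 1L)], nrow = nch)
      seg <- (seg - rowMeans(seg)) * rep(w, each = nch)
      X <- stats::mvfft(t(seg))[seq_len(nf), , drop = FALSE]
      Xc <- Conj(X)
      for (j in seq_len(nch)) S[, , j] <- S[, , j] + X * Xc[, j]
      nseg <- nseg + 1L
    }
  }
  list(freqs = seq(0, by = fs / nw, length.out = nf), S = S / nseg,
       n_segments = nseg)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

coherence_from_cross <- function(cs, i, j) {
  Sii <- Re(cs$S[, i, i]); Sjj <- Re(cs$S[, j, j])
  Mod(cs$S[, i, j])^2 / (Sii * Sjj)
}

#' Magnitude-squared coherence spectrum between two channels
#'
#' Estimates `C(f) = |S_xy(f)|^2 / (S_xx(f) S_yy(f))` with cross- and
#' auto-spectra obtained by Welch averaging across windows and retained
#' epochs. With a single averaging segment the estimator is identically 1
#' regardless of the data (the well-known coherence bias degeneracy), so at
#' least two segments are required.
#'
#' @param epochs A [new_epoch_set()].
#' @param ch_i,ch_j Channel indices or labels.
#' @param window_s,overlap,taper Welch parameters as in [welch_psd()].
#' @return List with `freqs` (Hz) and `coherence` (vector in `[0, 1]`).
#' @export
coherence_spectrum <- function(epochs, ch_i, ch_j, window_s = 2,
                               overlap = 0.5, taper = "hann") {
  i <- resolve_channel(epochs, ch_i)
  j <- resolve_channel(epochs, ch_j)
  cs <- welch_cross(epochs, window_s, overlap, taper)
  if (cs$n_segments < 2) {
    stop("coherence needs >= 2 averaging segments (single-segment coherence is identically 1)")
  }
  coh <- if (i == j) rep(1, length(cs$freqs)) else coherence_from_cross(cs, i, j)
  list(freqs = cs$freqs, coherence = pmin(1, pmax(0, coh)))
}

resolve_channel <- function(epochs, ch) {
  if (is.character(ch)) {
    idx <- match(ch, epochs$channel_labels)
    if (is.na(idx)) stop("unknown channel label: ", ch)
    idx
  } else as.integer(ch)
}

band_bins <- function(freqs, band) {
  sel <- which(freqs >= band$low - 1e-9 & freqs < band$high - 1e-9)
  if (!length(sel)) {
    stop(sprintf("band %s has no bins on the frequency grid", band$name))
  }
  sel
}

#' Band-averaged coherence matrix
#'
#' Builds the symmetric channels x channels connectivity matrix for one
#' frequency band: entry (i, j) is the mean of the coherence spectrum over
#' the bins inside `[band$low, band$high)`. The diagonal is set to 0 by
#' convention so downstream graph metrics never traverse self-loops.
#'
#' @param epochs A [new_epoch_set()] with >= 2 averaging segments.
#' @param band A [band_definition()].
#' @param window_s,overlap,taper Welch parameters.
#' @return Object of class `connectivity_matrix`: list with `C` (matrix),
#'   `band`, `n_epochs_used`.
#' @export
coherence_matrix <- function(epochs, band, window_s = 2, overlap = 0.5,
                             taper = "hann") {
  cs <- welch_cross(epochs, window_s, overlap, taper)
  if (cs$n_segments < 2) {
    stop("coherence needs >= 2 averaging segments (single-segment coherence is identically 1)")
  }
  C <- cross_to_band_matrix(cs, band)
  dimnames(C) <- list(epochs$channel_labels, epochs$channel_labels)
  structure(list(C = C, band = band,
                 n_epochs_used = dim(epochs$epochs)[1]),
            class = "connectivity_matrix")
}

cross_to_band_matrix <- function(cs, band) {
  sel <- band_bins(cs$freqs, band)
  nch <- dim(cs$S)[2]
  C <- matrix(0, nch, nch)
  for (i in seq_len(nch - 1)) {
    for (j in (i + 1):nch) {
      C[i, j] <- C[j, i] <- mean(pmin(1, coherence_from_cross(cs, i, j)[sel]))
    }
  }
  C
}

#' Per-epoch band coherence matrices
#'
#' One coherence matrix per retained epoch, estimated from the Welch
#' windows inside that epoch only. These per-epoch matrices are the pairing
#' unit for edge-wise paired statistics; note their common small-sample
#' bias (expected coherence of independent signals is about 1/L for L
#' windows), which cancels in paired pre/post comparisons.
#'
#' @inheritParams coherence_matrix
#' @return Array n_epochs x channels x channels.
#' @export
coherence_by_epoch <- function(epochs, band, window_s = 2, overlap = 0.5,
                               taper = "hann") {
  nep <- dim(epochs$epochs)[1]
  nch <- dim(epochs$epochs)[2]
  out <- array(NA_real_, c(nep, nch, nch),
               dimnames = list(NULL, epochs$channel_labels, epochs$channel_labels))
  for (e in seq_len(nep)) {
    cs <- welch_cross(epochs, window_s, overlap, taper, epoch_subset = e)
    if (cs$n_segments < 2) {
      stop("per-epoch coherence needs >= 2 windows per epoch")
    }
    out[e, , ] <- cross_to_band_matrix(cs, band)
  }
  out
}
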