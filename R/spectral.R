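#' @useDynLib seiznet, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

# Window taper for Welch segments.
taper_window <- function(n, taper = c("hann", "rect")) {
  taper <- match.arg(taper)
  if (taper == "hann") 0.5 - 0.5 * cos(2 * pi * seq(0, n - 1) / n) else rep(1, n)
}

# Start indices of Welch segments of length nw with fractional overlap
# inside an epoch of ns samples.
welch_starts <- function(ns, nw, overlap) {
  step <- max(1L, as.integer(round(nw * (1 - overlap))))
  seq.int(1L, ns - nw + 1L, by = step)
}

# Accumulate one-sided Welch auto-spectra over all windows of the retained
# epochs. Returns freqs (Hz) and psd (channels x freqs, uV^2/Hz).
welch_auto <- function(epochs, window_s, overlap, taper) {
  fs <- epochs$fs
  nw <- as.integer(round(window_s * fs))
  ns <- dim(epochs$epochs)[3]
  if (nw > ns) stop("window_s must not exceed the epoch length")
  nep <- dim(epochs$epochs)[1]
  if (nep < 1) stop("empty epoch set")
  w <- taper_window(nw, taper)
  U <- sum(w^2)
  nf <- nw %/% 2 + 1L
  starts <- welch_starts(ns, nw, overlap)
  nch <- dim(epochs$epochs)[2]
  acc <- matrix(0, nf, nch)
  nseg <- 0L
  for (e in seq_len(nep)) {
    for (s0 in starts) {
      seg <- t(epochs$epochs[e, , s0:(s0 + nw - 1L), drop = TRUE])
      if (nch == 1L) seg <- matrix(epochs$epochs[e, 1, s0:(s0 + nw - 1L)], ncol = 1)
      seg <- sweep(seg, 2, colMeans(seg), "-") * w
      X <- stats::mvfft(seg)[seq_len(nf), , drop = FALSE]
      acc <- acc + Mod(X)^2
      nseg <- nseg + 1L
    }
  }
  psd <- acc / (nseg * fs * U)
  # one-sided density: double all bins except DC and (for even nw) Nyquist
  dbl <- rep(2, nf); dbl[1] <- 1; if (nw %% 2 == 0) dbl[nf] <- 1
  psd <- psd * dbl
  list(freqs = seq(0, by = fs / nw, length.out = nf), psd = t(psd),
       n_segments = nseg)
}

#' Welch power spectral density of an epoch set
#'
#' Averages modified periodograms (mean-removed, tapered segments) across
#' overlapping windows within each retained epoch and across epochs. The
#' scaling is Parseval-consistent: the integral of the one-sided PSD over
#' frequency approximates the signal variance.
#'
#' @param epochs A [new_epoch_set()] with at least one retained epoch.
#' @param window_s Welch window length in seconds (default 2, giving 0.5 Hz
#'   resolution).
#' @param overlap Fractional window overlap (default 0.5).
#' @param taper `"hann"` (default) or `"rect"`.
#' @return An object of class `band_spectrum`: list with `freqs` (Hz),
#'   `psd` (channels x freqs, microvolts squared per Hz),
#'   `channel_labels`, and `n_epochs_used`.
#' @export
welch_psd <- function(epochs, window_s = 2, overlap = 0.5, taper = "hann") {
  a <- welch_auto(epochs, window_s, overlap, taper)
  structure(list(freqs = a$freqs, psd = a$psd,
                 channel_labels = epochs$channel_labels,
                 n_epochs_used = dim(epochs$epochs)[1]),
            class = "band_spectrum")
}

#' Aggregate a PSD into band powers
#'
#' Per channel and band, integrates the PSD across the band's frequency
#' grid points (edges inclusive) with the trapezoid rule. With the default
#' contiguous bands the five band powers sum exactly to the total 1-45 Hz
#' power.
#'
#' @param spectrum A [welch_psd()] result.
#' @param bands List of [band_definition()]s inside the spectrum range.
#' @param relative Divide each band power by the summed power over all
#'   requested bands (default FALSE: absolute microvolts squared).
#' @return An object of class `band_power`: list with `values` (channels x
#'   bands matrix) and `band_defs`.
#' @export
band_power <- function(spectrum, bands = default_bands(), relative = FALSE) {
  freqs <- spectrum$freqs
  vals <- sapply(bands, function(b) {
    if (b$low < min(freqs) - 1e-9 || b$high > max(freqs) + 1e-9) {
      stop(sprintf("band %s [%g, %g) outside spectrum range", b$name, b$low, b$high))
    }
    sel <- which(freqs >= b$low - 1e-9 & freqs <= b$high + 1e-9)
    if (length(sel) < 2) stop(sprintf("band %s has no bins on the frequency grid", b$name))
    apply(spectrum$psd[, sel, drop = FALSE], 1, function(p) {
      sum(diff(freqs[sel]) * (p[-1] + p[-length(p)]) / 2)
    })
  })
  vals <- matrix(vals, nrow = nrow(spectrum$psd),
                 dimnames = list(spectrum$channel_labels,
                                 vapply(bands, `[[`, character(1), "name")))
  if (relative) vals <- vals / rowSums(vals)
  structure(list(values = vals, band_defs = bands), class = "band_power")
}

#' Per-epoch band power
#'
#' Welch band power computed separately for every retained epoch; the
#' per-epoch values are the pairing unit for epoch-wise paired statistics.
#'
#' @inheritParams welch_psd
#' @param bands Band definitions.
#' @param log10 Return log10 power (default TRUE; variance-stabilizing for
#'   paired t-tests).
#' @return Array n_epochs x channels x bands.
#' @export
epoch_band_power <- function(epochs, bands = default_bands(), window_s = 2,
                             overlap = 0.5, taper = "hann", log10 = TRUE) {
  nep <- dim(epochs$epochs)[1]
  nch <- dim(epochs$epochs)[2]
  out <- array(NA_real_, c(nep, nch, length(bands)),
               dimnames = list(NULL, epochs$channel_labels,
                               vapply(bands, `[[`, character(1), "name")))
  for (e in seq_len(nep)) {
    one <- epochs
    one$epochs <- epochs$epochs[e, , , drop = FALSE]
    bp <- band_power(welch_psd(one, window_s, overlap, taper), bands)
    out[e, , ] <- bp$values
  }
  if (log10) log10(out) else out
}
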