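#' Fuzzy entropy parameters
#'
#' @param m Embedding dimension (>= 1); default 2.
#' @param r Tolerance as a fraction of the signal SD (> 0); default 0.2.
#' @param n_fuzz Fuzzy membership exponent (> 0); default 2.
#'
#' The defaults are the dominant convention in the EEG fuzzy-entropy
#' literature.
#'
#' @return List of class `fuzzyen_params`.
#' @export
fuzzyen_params <- function(m = 2, r = 0.2, n_fuzz = 2) {
  if (m < 1 || m != round(m)) stop("m must be a positive integer")
  if (r <= 0) stop("r must be > 0")
  if (n_fuzz <= 0) stop("n_fuzz must be > 0")
  structure(list(m = as.integer(m), r = r, n_fuzz = n_fuzz),
            class = "fuzzyen_params")
}

#' Fuzzy entropy of a single-channel signal
#'
#' Fuzzy entropy of a time series: form all baseline-removed templates of
#' length `m` and `m + 1`, measure template similarity with the smooth
#' membership `exp(-(d / r_abs)^n_fuzz)` of the Chebyshev distance `d`
#' (with `r_abs = r * SD(signal)`), average over all distinct template
#' pairs (self-matches excluded) to get `phi^m` and `phi^(m+1)`, and
#' return `ln(phi^m) - ln(phi^(m+1))` in nats. Higher values mean a more
#' irregular, less predictable signal.
#'
#' Because templates are mean-removed and the tolerance scales with the
#' signal SD, the measure is exactly invariant to additive offsets and to
#' positive rescaling of the signal.
#'
#' @param signal Numeric vector, length > m + 1, not constant.
#' @param params A [fuzzyen_params()].
#' @return Fuzzy entropy in nats (>= 0 in practice). A constant signal
#'   returns 0 with a warning (all template distances vanish).
#' @export
fuzzy_entropy <- function(signal, params = fuzzyen_params()) {
  stopifnot(inherits(params, "fuzzyen_params"))
  signal <- as.numeric(signal)
  if (length(signal) <= params$m + 1) {
    stop("signal must be longer than m + 1 samples")
  }
  s <- stats::sd(signal)
  if (s == 0) {
    warning("constant signal: fuzzy entropy defined as 0")
    return(0)
  }
  phi <- fuzzyen_phi(signal, params$m, params$r * s, params$n_fuzz)
  log(phi[1]) - log(phi[2])
}

#' Fuzzy entropy of an epoch set, optionally band-limited
#'
#' Computes fuzzy entropy per channel and retained epoch, optionally after
#' zero-phase band-pass filtering each epoch to a frequency band (delta by
#' default use in the pipeline), and averages over epochs.
#'
#' When a band is given, each filtered epoch is also decimated to roughly
#' four times the band's upper edge (factor `floor(fs / (4 * band$high))`,
#' if > 1). A band-limited signal at the full sampling rate is heavily
#' oversampled — neighbouring samples are nearly identical, lag-1 template
#' distances collapse, and fuzzy entropy saturates near zero, blind to the
#' in-band structure. Decimating to a rate commensurate with the band
#' restores sensitivity; no further anti-aliasing is needed since the
#' signal is already band-limited.
#'
#' @param epochs A [new_epoch_set()] with >= 1 retained epoch.
#' @param params A [fuzzyen_params()].
#' @param band A [band_definition()] to filter each epoch-channel to before
#'   entropy, or `NULL` for broadband.
#' @param channels Channel indices/labels to compute (default all).
#' @param decimate Decimate band-filtered epochs as described (default
#'   TRUE; ignored for broadband).
#' @return Object of class `entropy_result`: list with `values` (named
#'   per-channel mean over epochs), `per_epoch` (n_epochs x channels
#'   matrix), `params`, `band`.
#' @export
epoch_entropy <- function(epochs, params = fuzzyen_params(), band = NULL,
                          channels = NULL, decimate = TRUE) {
  nep <- dim(epochs$epochs)[1]
  if (nep < 1) stop("empty epoch set")
  chs <- if (is.null(channels)) seq_len(dim(epochs$epochs)[2]) else
    vapply(channels, function(ch) resolve_channel(epochs, ch), integer(1))
  dec <- if (!is.null(band) && decimate) {
    max(1L, as.integer(epochs$fs %/% (4 * band$high)))
  } else 1L
  spw <- dim(epochs$epochs)[3]
  # filter all (epoch, channel) series in one vectorized pass
  flat <- matrix(aperm(epochs$epochs[, chs, , drop = FALSE], c(3, 1, 2)),
                 nrow = spw)
  if (!is.null(band)) {
    flat <- bandpass_matrix(flat, epochs$fs, band$low, band$high)
  }
  if (dec > 1L) flat <- flat[seq(1L, spw, by = dec), , drop = FALSE]
  per <- matrix(NA_real_, nep, length(chs),
                dimnames = list(NULL, epochs$channel_labels[chs]))
  for (e in seq_len(nep)) {
    for (k in seq_along(chs)) {
      per[e, k] <- fuzzy_entropy(flat[, (k - 1L) * nep + e], params)
    }
  }
  structure(list(values = colMeans(per), per_epoch = per, params = params,
                 band = band),
            class = "entropy_result")
}
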