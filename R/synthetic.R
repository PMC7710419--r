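#' Pre/post-seizure effect specification for the synthetic generator
#'
#' Encodes, as plantable ground truth, the qualitative peri-ictal contrasts
#' the analysis pipeline is meant to detect: a post-seizure delta-power
#' increase, a post-seizure complexity (fuzzy entropy) decrease, additive
#' coupling changes on chosen channel pairs, and a monotone scaling of those
#' coupling changes across consecutive seizures.
#'
#' @param delta_power_ratio Multiplicative post/pre delta-band variance
#'   factor, scalar or one per channel; must be > 0. 1 = no effect.
#' @param entropy_shift Per-channel relative change of the broadband-to-
#'   oscillation ratio `q` in the post state (`q_post = q * (1 +
#'   entropy_shift)`); negative values concentrate band power on the narrow
#'   rhythm and lower fuzzy entropy. Scalar or one per channel; must keep
#'   `q_post > 0`.
#' @param edge_shifts Symmetric zero-diagonal matrix (or named list of such
#'   matrices per band) of additive coupling change in the post state;
#'   negative = weakened, positive = enhanced.
#' @param seizure_trend Scalar; coupling applied for segment order
#'   t (1-pre = 1, 1-post = 2, 2-pre = 3, ...) is
#'   `coupling + edge_shifts * (I(post) + seizure_trend * (t - 1))`, so a
#'   nonzero trend plants monotone network change across consecutive
#'   seizures.
#' @return A list of class `pre_post_effect`.
#' @export
pre_post_effect <- function(delta_power_ratio = 1, entropy_shift = 0,
                            edge_shifts = NULL, seizure_trend = 0) {
  if (any(delta_power_ratio <= 0)) stop("delta_power_ratio must be > 0")
  if (any(1 + entropy_shift <= 0)) stop("entropy_shift must keep 1 + shift > 0")
  structure(list(delta_power_ratio = delta_power_ratio,
                 entropy_shift = entropy_shift,
                 edge_shifts = edge_shifts,
                 seizure_trend = seizure_trend),
            class = "pre_post_effect")
}

#' Configuration for the synthetic EEG generator
#'
#' Describes a band-structured, optionally coupled multichannel EEG process.
#' Each channel is a sum over frequency bands of band-limited sources plus
#' white measurement noise. Within a band, a channel mixes its own source
#' with shared pair sources; mixing weights are chosen so the analytic
#' magnitude-squared coherence at band centre equals the requested coupling
#' (see [generate_recording()]).
#'
#' @param n_channels Number of channels (default 16, the 10-20 montage).
#' @param fs Sampling rate in Hz (default 256); must exceed twice the
#'   highest band edge.
#' @param duration Recording length in seconds (default 600 = 10 min);
#'   `duration * fs` must be an integer.
#' @param band_powers Named list band -> per-channel signal variance in
#'   microvolts squared (scalars are recycled across channels). Defaults
#'   give a delta-dominant spectrum with total SD about 12 microvolts,
#'   comfortably inside the +/-80 microvolt artifact threshold.
#' @param coupling Symmetric matrix in `[0, 1)` with zero diagonal of target
#'   band-centre magnitude-squared coherence per channel pair (applied to
#'   every band), or a named list of such matrices per band. Default: no
#'   coupling.
#' @param noise_sd White measurement noise SD in microvolts (default 5).
#' @param q Broadband-to-oscillation power ratio inside each band (default
#'   1): each band source mixes a narrow rhythm at band centre with the
#'   full-band component in proportion `1 : q`. Larger `q` means a flatter
#'   in-band spectrum and higher fuzzy entropy.
#' @param artifact_rate Expected fraction of 6-s windows to corrupt when
#'   [inject_artifacts()] is driven from the config (default 0).
#' @param effect A [pre_post_effect()] (default: all null).
#' @param bands Band definitions, [default_bands()] by default.
#' @param seed Integer seed; generation is a pure function of
#'   (config, state, seizure_index).
#' @return A validated list of class `synth_config`.
#' @export
synth_config <- function(n_channels = 16, fs = 256, duration = 600,
                         band_powers = list(delta = 50, theta = 25, alpha = 30,
                                            beta = 15, low_gamma = 5),
                         coupling = NULL, noise_sd = 5, q = 1,
                         artifact_rate = 0, effect = pre_post_effect(),
                         bands = default_bands(), seed = 1L) {
  check_bands(bands)
  if (!all(names(band_powers) %in% names(bands))) {
    stop("band_powers names must match band names")
  }
  hi <- max(vapply(bands, `[[`, numeric(1), "high"))
  if (fs <= 2 * hi) stop("fs must exceed twice the highest band edge")
  if (abs(duration * fs - round(duration * fs)) > 1e-9) {
    stop("duration * fs must be an integer sample count")
  }
  if (!is.null(coupling)) {
    mats <- if (is.matrix(coupling)) list(coupling) else coupling
    for (m in mats) check_coupling_matrix(m, n_channels)
  }
  if (artifact_rate < 0 || artifact_rate > 1) stop("artifact_rate must be in [0, 1]")
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  if (q <= 0) stop("q must be > 0")
  structure(list(n_channels = n_channels, fs = fs, duration = duration,
                 band_powers = band_powers, coupling = coupling,
                 noise_sd = noise_sd, q = q, artifact_rate = artifact_rate,
                 effect = effect, bands = bands, seed = as.integer(seed)),
            class = "synth_config")
}

check_coupling_matrix <- function(m, n_channels, what = "coupling") {
  if (!is.matrix(m) || nrow(m) != n_channels || ncol(m) != n_channels) {
    stop(what, " must be an n_channels x n_channels matrix")
  }
  if (max(abs(m - t(m))) > 1e-12) stop(what, " must be symmetric")
  if (any(diag(m) != 0)) stop(what, " must have a zero diagonal")
  if (startsWith(what, "coupling") && (any(m < 0) || any(m >= 1))) {
    stop(what, " entries must lie in [0, 1)")
  }
  invisible(m)
}

# Matrix for band `bn` out of a matrix-or-list spec; zero matrix when absent.
band_matrix <- function(x, bn, n) {
  if (is.null(x)) return(matrix(0, n, n))
  if (is.matrix(x)) return(x)
  if (!is.null(x[[bn]])) return(x[[bn]]) else matrix(0, n, n)
}

recycle_ch <- function(x, n) {
  if (length(x) == 1L) rep(x, n) else if (length(x) == n) x else
    stop("per-channel parameter must have length 1 or n_channels")
}

#' Band-limited Gaussian noise via a zero-phase 4th-order Butterworth response
#'
#' Generates columns of unit-variance Gaussian noise confined to
#' `[low, high]` Hz by applying the squared magnitude response of a
#' 4th-order digital Butterworth band-pass (i.e. the forward-backward
#' filter) in the frequency domain. Columns are independent and normalized
#' to unit sample variance.
#'
#' @param n Number of samples.
#' @param fs Sampling rate (Hz).
#' @param low,high Pass-band edges (Hz).
#' @param ncols Number of independent columns.
#' @return An `n x ncols` numeric matrix.
#' @keywords internal
narrowband_noise <- function(n, fs, low, high, ncols = 1L) {
  sp <- rand_band_spectrum(n, fs, low, high, ncols)
  half_spectrum_to_time(sp, n)
}

# cache of |H|^2 grids (positive-frequency half) keyed by (n, fs, low, high)
.h2_cache <- new.env(parent = emptyenv())

# Squared magnitude response of the 4th-order digital Butterworth band-pass
# applied forward-backward (signal::filtfilt), on the positive-frequency
# DFT bins 2..n/2 (+1 offset for R indexing; DC and Nyquist excluded), with
# the numerically-zero tail (< 1e-10 of peak) truncated to a support set.
butter_response2 <- function(n, fs, low, high) {
  key <- paste(n, fs, low, high, sep = "_")
  if (!is.null(.h2_cache[[key]])) return(.h2_cache[[key]])
  bf <- signal::butter(4, c(low, high) / (fs / 2), type = "pass")
  nh <- n %/% 2
  w <- 2 * pi * seq_len(nh - 1) / n
  ek <- exp(-1i * outer(w, seq_along(bf$b) - 1))
  H2 <- as.vector(Mod((ek %*% bf$b) / (ek %*% bf$a))^2)
  idx <- which(H2 > 1e-10 * max(H2))
  out <- list(idx = idx + 1L, H2 = H2[idx])   # idx in 1-based full-grid bins
  .h2_cache[[key]] <- out
  out
}

# Band-limited Gaussian noise drawn directly in the frequency domain: the
# DFT of iid Gaussian noise is iid complex Gaussian (the DFT is orthogonal),
# so sampling complex Gaussians on the filter support and scaling by |H|^2
# realizes exactly the same process as forward-backward filtering white
# noise, at a fraction of the cost. Columns are normalized to unit sample
# variance via Parseval. Returns list(idx, vals) on positive-frequency bins.
rand_band_spectrum <- function(n, fs, low, high, ncols) {
  h <- butter_response2(n, fs, low, high)
  rand_spectrum(h, n, ncols)
}

rand_spectrum <- function(h, n, ncols) {
  m <- length(h$idx)
  Z <- matrix(complex(real = stats::rnorm(m * ncols),
                      imaginary = stats::rnorm(m * ncols)), m, ncols)
  X <- Z * h$H2
  # sample variance of the real signal: 2 sum |X_k|^2 / n^2 over the half
  nrm <- sqrt(2 * colSums(Mod(X)^2) / n^2)
  list(idx = h$idx, vals = sweep(X, 2, nrm, "/"))
}

# Narrow "rhythm" line source: Gaussian spectral envelope at the band
# centre. sigma_hz trades off the fuzzy-entropy handle (narrower = more
# sinusoidal = lower entropy) against phase decorrelation (~1/(2 sigma) s):
# it must stay well below the recording length so independent channels
# average to zero coherence under pooled Welch estimation.
rand_line_spectrum <- function(n, fs, ctr, sigma_hz, ncols) {
  key <- paste("g", n, fs, ctr, sigma_hz, sep = "_")
  h <- .h2_cache[[key]]
  if (is.null(h)) {
    f <- seq_len(n %/% 2 - 1) * fs / n
    H2 <- exp(-0.5 * ((f - ctr) / sigma_hz)^2)
    idx <- which(H2 > 1e-10)
    h <- list(idx = idx + 1L, H2 = H2[idx])
    .h2_cache[[key]] <- h
  }
  rand_spectrum(h, n, ncols)
}

# Inverse transform of a positive-frequency half spectrum (Hermitian
# completion) to a real n-sample signal matrix.
half_spectrum_to_time <- function(sp, n) {
  ncols <- ncol(sp$vals)
  X <- matrix(0 + 0i, n, ncols)
  X[sp$idx, ] <- sp$vals
  X[n + 2L - sp$idx, ] <- Conj(sp$vals)
  Re(stats::mvfft(X, inverse = TRUE)) / n
}

# Add weighted half-spectrum columns into the accumulator (rows = DFT bins
# 2..n/2, i.e. bin r at row r - 1).
acc_add <- function(A, sp, weights, cols = NULL) {
  rows <- sp$idx - 1L
  if (is.null(cols)) {
    A[rows, ] <- A[rows, ] + sweep(sp$vals, 2, weights, "*")
  } else {
    for (k in seq_along(cols)) {
      A[rows, cols[k]] <- A[rows, cols[k]] + weights[k] * sp$vals[, k]
    }
  }
  A
}

# Shared-source mixing weights for one band.
#
# Channel i's band signal (before the power scaling sqrt(P_i)) is
#   z_i = a_i * u_i + sum_j b_ij * s_ij,   a_i^2 + sum_j b_ij^2 = 1,
# with u_i, s_ij independent unit-variance sources of equal spectrum.
# At band centre the source PSD is S_u and the white-noise PSD is
# Sn = noise_sd^2 / (fs/2), so with rho_i = Sn / (P_i * S_u) the
# magnitude-squared coherence of the pair is
#   C_ij = b_ij^4 / ((1 + rho_i) (1 + rho_j)).
# Inverting gives b_ij^2 = sqrt(kappa_ij * (1 + rho_i) * (1 + rho_j));
# the request is infeasible when b_ij^2 > 1 or a channel's shared weights
# exceed unit total power.
coupling_weights <- function(kappa, rho, band_name) {
  n <- nrow(kappa)
  b2 <- sqrt(kappa * outer(1 + rho, 1 + rho))
  bad <- which(b2 > 1 & upper.tri(b2), arr.ind = TRUE)
  if (nrow(bad)) {
    stop(sprintf(
      "infeasible coupling in band %s for pair (%d, %d): target coherence %.3f not achievable given noise_sd",
      band_name, bad[1, 1], bad[1, 2], kappa[bad[1, 1], bad[1, 2]]))
  }
  shared_power <- rowSums(b2)
  if (any(shared_power > 1)) {
    ch <- which.max(shared_power)
    prs <- which(b2[ch, ] > 0)
    stop(sprintf(
      "infeasible coupling in band %s: channel %d's pairs (%s) need total shared power %.2f > 1",
      band_name, ch, paste(prs, collapse = ", "), shared_power[ch]))
  }
  list(b = sqrt(b2), a = sqrt(1 - shared_power))
}

#' Generate one synthetic EEG recording
#'
#' Realizes the process described by a [synth_config()] for a given state
#' (`"pre"` or `"post"`) and seizure index. Pairwise coupling is realized by
#' mixing band-limited shared sources; the mixing weight for a pair is
#' chosen so the analytic magnitude-squared coherence at band centre equals
#' the configured coupling (see the weight derivation in the source of
#' `coupling_weights()`). Post-state recordings additionally carry the
#' configured [pre_post_effect()]: delta variance scaled by
#' `delta_power_ratio`, per-channel `q` scaled by `1 + entropy_shift`, and
#' coupling shifted by `edge_shifts` (scaled by `seizure_trend` and segment
#' order). Generation is a pure function of (config, state, seizure_index).
#'
#' @param config A [synth_config()].
#' @param state `"pre"` or `"post"`.
#' @param seizure_index Seizure number, >= 1.
#' @return A [new_recording()]; `$id` is `"<seizure_index>-<state>"`.
#' @export
generate_recording <- function(config, state = c("pre", "post"),
                               seizure_index = 1L) {
  stopifnot(inherits(config, "synth_config"))
  state <- match.arg(state)
  if (seizure_index < 1) stop("seizure_index must be >= 1")
  post <- state == "post"
  torder <- 2L * (seizure_index - 1L) + if (post) 2L else 1L

  nch <- config$n_channels
  n <- as.integer(round(config$duration * config$fs))
  eff <- config$effect
  trend_scale <- (if (post) 1 else 0) + eff$seizure_trend * (torder - 1)

  q_ch <- rep(config$q, nch)
  if (post) q_ch <- q_ch * (1 + recycle_ch(eff$entropy_shift, nch))

  seed <- (abs(config$seed) * 97L + seizure_index * 1031L + post) %%
    .Machine$integer.max
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)

  sn_psd <- config$noise_sd^2 / (config$fs / 2)
  nh <- n %/% 2
  A <- matrix(0 + 0i, nh - 1L, nch)    # per-channel half spectra, bins 2..n/2
  for (bn in names(config$band_powers)) {
    band <- config$bands[[bn]]
    pw <- recycle_ch(config$band_powers[[bn]], nch)
    if (bn == "delta" && post) {
      pw <- pw * recycle_ch(eff$delta_power_ratio, nch)
    }
    kappa <- band_matrix(config$coupling, bn, nch) +
      trend_scale * band_matrix(eff$edge_shifts, bn, nch)
    check_coupling_matrix(kappa, nch,
                          what = sprintf("coupling (band %s, segment %s)", bn, torder))

    # source PSD at band centre, flat-in-band approximation
    s_u <- 1 / (band$high - band$low)
    rho <- ifelse(pw > 0, sn_psd / (pw * s_u), 0)
    wts <- coupling_weights(kappa, rho, bn)

    ctr <- (band$low + band$high) / 2
    sig <- (band$high - band$low) / 80
    own_n <- rand_line_spectrum(n, config$fs, ctr, sig, nch)
    own_b <- rand_band_spectrum(n, config$fs, band$low, band$high, nch)
    A <- acc_add(A, own_n, wts$a * sqrt(1 / (1 + q_ch)) * sqrt(pw))
    A <- acc_add(A, own_b, wts$a * sqrt(q_ch / (1 + q_ch)) * sqrt(pw))

    prs <- which(wts$b > 0 & upper.tri(wts$b), arr.ind = TRUE)
    if (nrow(prs)) {
      qp <- sqrt(q_ch[prs[, 1]] * q_ch[prs[, 2]])
      sh_n <- rand_line_spectrum(n, config$fs, ctr, sig, nrow(prs))
      sh_b <- rand_band_spectrum(n, config$fs, band$low, band$high, nrow(prs))
      for (side in 1:2) {
        ch <- prs[, side]
        b_ij <- wts$b[prs]
        A <- acc_add(A, sh_n, b_ij * sqrt(1 / (1 + qp)) * sqrt(pw[ch]), cols = ch)
        A <- acc_add(A, sh_b, b_ij * sqrt(qp / (1 + qp)) * sqrt(pw[ch]), cols = ch)
      }
    }
  }
  X <- matrix(0 + 0i, n, nch)
  X[2:nh, ] <- A
  X[n + 2L - (2:nh), ] <- Conj(A)
  x <- t(Re(stats::mvfft(X, inverse = TRUE)) / n)
  x <- x + matrix(stats::rnorm(nch * n, 0, config$noise_sd), nch, n)

  new_recording(x, config$fs, id = sprintf("%d-%s", seizure_index, state))
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
}
.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", globalenv())) rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}

#' Inject high-amplitude artifacts into chosen 6-s windows
#'
#' Corrupts `round(rate * n_windows)` windows (chosen uniformly without
#' replacement) with a burst of alternating square pulses (three 4 Hz
#' cycles) followed by a linear ramp, of the stated amplitude, on one
#' random channel. The burst's energy sits inside the 1-45 Hz analysis
#' band, so the excursion survives the preprocessing filter at full
#' amplitude (a single long plateau would lose half its height to the 1 Hz
#' high-pass); it is placed 2 s into the window so zero-phase filtering
#' cannot leak it into neighbouring windows. Returns both the corrupted
#' recording and the exact planted window indices so artifact rejection can
#' be verified against ground truth.
#'
#' @param recording A [new_recording()].
#' @param rate Fraction of windows to corrupt, in `[0, 1]`.
#' @param amplitude Pulse amplitude in microvolts; must exceed 80 so the
#'   planted windows trip the rejection threshold.
#' @param seed Integer seed for window/channel/sign choices.
#' @param epoch_length Window length in seconds (default 6, matching
#'   [segment_epochs()]).
#' @return List with `recording` (corrupted copy) and `windows` (sorted
#'   integer indices of planted windows, 1-based in segmentation order).
#' @export
inject_artifacts <- function(recording, rate, amplitude = 150, seed = 1L,
                             epoch_length = 6) {
  if (rate < 0 || rate > 1) stop("rate must be in [0, 1]")
  if (amplitude <= 80) stop("amplitude must exceed 80 microvolts to trip the rejection rule")
  fs <- recording$fs
  spw <- as.integer(round(epoch_length * fs))
  n_windows <- floor(ncol(recording$data) / spw)
  count <- round(rate * n_windows)
  if (count == 0) {
    return(list(recording = recording, windows = integer(0)))
  }
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  windows <- sort(sample.int(n_windows, count))
  data <- recording$data
  # three 4 Hz square cycles + quarter-second ramp; 2 s margins both sides
  per <- as.integer(round(fs / 4))
  burst <- rep(c(rep(1, per %/% 2L), rep(-1, per - per %/% 2L)), 3L)
  shape <- c(burst, seq(1, 0, length.out = as.integer(fs %/% 4)) * burst[length(burst)])
  for (w in windows) {
    ch <- sample.int(nrow(data), 1L)
    sgn <- sample(c(-1, 1), 1L)
    idx <- (w - 1L) * spw + as.integer(round(2 * fs)) + seq_along(shape)
    data[ch, idx] <- data[ch, idx] + sgn * amplitude * shape
  }
  out <- recording
  out$data <- data
  list(recording = out, windows = windows)
}

#' Generate a consecutive-seizure series of pre/post recording pairs
#'
#' Produces `2 * n_seizures` recordings labeled `1-pre`, `1-post`, ...,
#' `k-post`. With a nonzero `seizure_trend` in the config's effect, the
#' planted coupling change grows monotonically with segment order, planting
#' a monotone network degradation across consecutive seizures.
#'
#' @param config A [synth_config()].
#' @param n_seizures Number of seizures, >= 2.
#' @return Named list of [new_recording()] objects in temporal order
#'   (`"1-pre"`, `"1-post"`, ...).
#' @export
generate_seizure_series <- function(config, n_seizures) {
  if (n_seizures < 2) stop("n_seizures must be >= 2")
  out <- list()
  for (s in seq_len(n_seizures)) {
    for (state in c("pre", "post")) {
      rec <- generate_recording(config, state, s)
      out[[rec$id]] <- rec
    }
  }
  out
}
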