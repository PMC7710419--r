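# Independent reference implementations used to cross-check the package.
# These deliberately stay naive (double loops, literal formulas).

# Fuzzy entropy, literal O(N^2) double loop over baseline-removed templates.
fuzzyen_oracle <- function(x, m, r_abs, n_fuzz = 2) {
  N <- length(x)
  nt <- N - m
  phi <- function(mm) {
    tpl <- matrix(0, mm, nt)
    for (i in seq_len(nt)) {
      v <- x[i:(i + mm - 1)]
      tpl[, i] <- v - mean(v)
    }
    tot <- 0
    for (i in 1:(nt - 1)) {
      for (j in (i + 1):nt) {
        d <- max(abs(tpl[, i] - tpl[, j]))
        tot <- tot + exp(-(d / r_abs)^n_fuzz)
      }
    }
    tot / (nt * (nt - 1) / 2)
  }
  log(phi(m)) - log(phi(m + 1))
}

# Benjamini-Hochberg step-up, literal: adj_i = min_{j >= i} p_(j) * m / j.
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- numeric(m)
  run_min <- 1
  for (i in m:1) {
    run_min <- min(run_min, p[o[i]] * m / i)
    adj[o[i]] <- run_min
  }
  pmin(adj, 1)
}

# All-pairs shortest paths by Floyd-Warshall on lengths 1/w.
fw_cpl_oracle <- function(C) {
  n <- nrow(C)
  d <- matrix(Inf, n, n)
  d[C > 0] <- 1 / C[C > 0]
  diag(d) <- 0
  for (k in 1:n) for (i in 1:n) for (j in 1:n) {
    if (d[i, k] + d[k, j] < d[i, j]) d[i, j] <- d[i, k] + d[k, j]
  }
  mean(d[row(d) != col(d)])
}

# Clustering coefficient by literal triple loop, both normalizations.
cc_oracle <- function(C, variant) {
  n <- nrow(C)
  terms <- numeric(n)
  for (i in 1:n) {
    num <- 0
    for (j in 1:n) for (h in 1:n) {
      num <- num + (C[i, j] * C[i, h] * C[j, h])^(1 / 3)
    }
    den <- if (variant == "printed") {
      s <- sum(C[i, ])
      s * (s - 1)
    } else {
      k <- sum(C[i, ] > 0)
      k * (k - 1)
    }
    terms[i] <- if (den > 0) num / den else 0
  }
  mean(terms)
}

# Direct (single-segment, rectangular) one-sided periodogram, uV^2/Hz.
periodogram_oracle <- function(x, fs) {
  n <- length(x)
  x <- x - mean(x)
  X <- stats::fft(x)
  nf <- n %/% 2 + 1
  p <- Mod(X[1:nf])^2 / (n * fs)
  dbl <- rep(2, nf); dbl[1] <- 1; if (n %% 2 == 0) dbl[nf] <- 1
  list(freqs = seq(0, by = fs / n, length.out = nf), psd = p * dbl)
}

# Naive Welch cross-spectral matrix: explicit accumulation loop over
# epochs/windows for a channel pair; mirrors Eq.-style C = |Sxy|^2/(Sxx Syy).
coherence_oracle <- function(epochs, i, j, window_s, overlap, taper = "hann") {
  fs <- epochs$fs
  nw <- round(window_s * fs)
  w <- if (taper == "hann") 0.5 - 0.5 * cos(2 * pi * seq(0, nw - 1) / nw) else rep(1, nw)
  step <- max(1, round(nw * (1 - overlap)))
  nf <- nw %/% 2 + 1
  sxx <- syy <- rep(0, nf)
  sxy <- rep(0 + 0i, nf)
  for (e in seq_len(dim(epochs$epochs)[1])) {
    s0 <- 1
    while (s0 + nw - 1 <= dim(epochs$epochs)[3]) {
      xi <- epochs$epochs[e, i, s0:(s0 + nw - 1)]
      xj <- epochs$epochs[e, j, s0:(s0 + nw - 1)]
      Xi <- stats::fft((xi - mean(xi)) * w)[1:nf]
      Xj <- stats::fft((xj - mean(xj)) * w)[1:nf]
      sxx <- sxx + Mod(Xi)^2
      syy <- syy + Mod(Xj)^2
      sxy <- sxy + Xi * Conj(Xj)
      s0 <- s0 + step
    }
  }
  Mod(sxy)^2 / (sxx * syy)
}

# Small epoch-set fixture of iid Gaussian noise.
noise_epochs <- function(n_epochs, n_channels = 2, epoch_s = 2, fs = 64,
                         sd = 1) {
  spw <- epoch_s * fs
  arr <- array(stats::rnorm(n_epochs * n_channels * spw, sd = sd),
               c(n_epochs, n_channels, spw))
  new_epoch_set(arr, epoch_s, fs, paste0("ch", seq_len(n_channels)))
}

# Random symmetric connectivity-like matrix with zero diagonal.
random_conn <- function(n = 16, density = 1, max_w = 1) {
  C <- matrix(stats::runif(n * n, 0, max_w), n, n)
  if (density < 1) C[matrix(stats::runif(n * n) > density, n, n)] <- 0
  C <- (C + t(C)) / 2
  diag(C) <- 0
  C
}
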