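test_that("self-coherence is 1 and single-segment estimation is refused", {
  set.seed(1)
  ep <- noise_epochs(10, n_channels = 2, epoch_s = 2, fs = 64)
  cs <- coherence_spectrum(ep, 1, 1, window_s = 1)
  expect_true(all(cs$coherence == 1))

  one <- noise_epochs(1, n_channels = 2, epoch_s = 2, fs = 64)
  expect_error(coherence_spectrum(one, 1, 2, window_s = 2, overlap = 0),
               "averaging segments")
})

test_that("independent channels show near-zero pooled coherence", {
  set.seed(2)
  ep <- noise_epochs(100, n_channels = 2, epoch_s = 2, fs = 64)
  cs <- coherence_spectrum(ep, 1, 2, window_s = 1)
  expect_lt(mean(cs$coherence), 0.1)
})

test_that("magnitude-squared coherence is invariant to a pure delay", {
  set.seed(3)
  n <- 40 * 64
  x <- as.vector(stats::filter(rnorm(n + 3), rep(1 / 3, 3), sides = 1))
  x[is.na(x)] <- 0
  y <- c(rep(0, 3), x[1:n])          # x delayed by 3 samples, no noise
  arr <- array(0, c(20, 2, 128))
  for (e in 1:20) {
    idx <- ((e - 1) * 128 + 1):(e * 128)
    arr[e, 1, ] <- x[idx]
    arr[e, 2, ] <- y[idx]
  }
  ep <- new_epoch_set(arr, 2, 64, c("a", "b"))
  cs <- coherence_spectrum(ep, 1, 2, window_s = 1)
  mid <- cs$freqs > 4 & cs$freqs < 20
  expect_gt(mean(cs$coherence[mid]), 0.9)
})

test_that("coherence matches the naive accumulation-loop reference", {
  set.seed(4)
  ep <- noise_epochs(5, n_channels = 3, epoch_s = 2, fs = 32)
  cs <- coherence_spectrum(ep, 1, 3, window_s = 1, overlap = 0.5)
  want <- coherence_oracle(ep, 1, 3, window_s = 1, overlap = 0.5)
  expect_equal(cs$coherence, pmin(1, want), tolerance = 1e-12)
})

test_that("identical channels give an all-ones off-diagonal matrix", {
  set.seed(5)
  x <- rnorm(10 * 128)
  arr <- array(0, c(10, 3, 128))
  for (e in 1:10) for (ch in 1:3) arr[e, ch, ] <- x[((e - 1) * 128 + 1):(e * 128)]
  ep <- new_epoch_set(arr, 2, 64, c("a", "b", "c"))
  cm <- coherence_matrix(ep, band_definition("mid", 4, 20), window_s = 1)
  off <- cm$C[upper.tri(cm$C)]
  expect_true(all(abs(off - 1) < 1e-9))
  expect_true(all(diag(cm$C) == 0))
  expect_equal(cm$C, t(cm$C))
})

test_that("the coherence matrix is invariant to epoch order", {
  set.seed(6)
  ep <- noise_epochs(8, n_channels = 3, epoch_s = 2, fs = 64)
  b <- band_definition("mid", 4, 20)
  c1 <- coherence_matrix(ep, b, window_s = 1)
  perm <- ep; perm$epochs <- ep$epochs[sample(8), , , drop = FALSE]
  c2 <- coherence_matrix(perm, b, window_s = 1)
  expect_equal(c1$C, c2$C, tolerance = 1e-12)
})

test_that("small-sample coherence bias of independent signals is ~1/L", {
  set.seed(8)
  L <- 8
  reps <- sapply(1:30, function(i) {
    ep <- noise_epochs(L, n_channels = 2, epoch_s = 2, fs = 64)
    cs <- coherence_spectrum(ep, 1, 2, window_s = 2, overlap = 0)
    mean(cs$coherence)
  })
  expect_lt(abs(mean(reps) - 1 / L), 0.5 / L)
})

test_that("per-epoch matrices carry the window-count bias and stack correctly", {
  set.seed(9)
  ep <- noise_epochs(12, n_channels = 2, epoch_s = 2, fs = 64)
  arr <- coherence_by_epoch(ep, band_definition("mid", 4, 20), window_s = 1,
                            overlap = 0)
  expect_equal(dim(arr), c(12, 2, 2))
  # 2 windows per epoch -> bias ~ 1/2 for independent channels
  expect_lt(abs(mean(arr[, 1, 2]) - 0.5), 0.25)
})
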