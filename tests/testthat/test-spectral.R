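test_that("Welch PSD is Parseval-consistent on white noise", {
  set.seed(42)
  ints <- replicate(5, {
    ep <- noise_epochs(20, n_channels = 1, epoch_s = 2, fs = 256)
    sp <- welch_psd(ep, window_s = 1)
    sum(diff(sp$freqs) * (sp$psd[1, -1] + sp$psd[1, -length(sp$freqs)]) / 2)
  })
  expect_lt(abs(mean(ints) - 1), 0.1)
})

test_that("a pure sinusoid concentrates ~A^2/2 power at its frequency", {
  fs <- 256
  A <- 3
  t <- seq(0, 6 - 1 / fs, by = 1 / fs)
  x <- A * sin(2 * pi * 10 * t)
  ep <- new_epoch_set(array(x, c(1, 1, length(x))), 6, fs, "ch1")
  sp <- welch_psd(ep, window_s = 2)
  near <- which(abs(sp$freqs - 10) <= 1)   # peak plus taper leakage
  pk <- sum(sp$psd[1, near]) * (fs / 512)
  expect_lt(abs(pk - A^2 / 2) / (A^2 / 2), 0.05)
})

test_that("Welch reduces to the direct periodogram in the degenerate case", {
  set.seed(7)
  fs <- 64
  x <- rnorm(2 * fs)
  ep <- new_epoch_set(array(x, c(1, 1, length(x))), 2, fs, "ch1")
  sp <- welch_psd(ep, window_s = 2, overlap = 0, taper = "rect")
  or <- periodogram_oracle(x, fs)
  expect_equal(sp$freqs, or$freqs)
  expect_equal(as.vector(sp$psd[1, ]), or$psd, tolerance = 1e-12)
})

test_that("band power integrates the PSD and partitions the 1-45 Hz range", {
  freqs <- seq(0, 128, by = 0.5)
  flat <- structure(list(freqs = freqs,
                         psd = matrix(1, 1, length(freqs)),
                         channel_labels = "ch1", n_epochs_used = 1),
                    class = "band_spectrum")
  bp <- band_power(flat)
  expect_equal(bp$values[1, "delta"], 3)
  expect_equal(bp$values[1, "low_gamma"], 15)

  zero <- flat; zero$psd[] <- 0
  expect_true(all(band_power(zero)$values == 0))

  # contiguous bands partition the full filtered range
  total <- band_power(flat, list(band_definition("all", 1, 45)))
  expect_equal(sum(bp$values), total$values[1, 1])

  expect_error(band_power(flat, list(band_definition("hf", 100, 200))),
               "outside")
})

test_that("band power scales quadratically with amplitude and ignores epoch order", {
  set.seed(11)
  ep <- noise_epochs(6, n_channels = 2, epoch_s = 2, fs = 128)
  bp1 <- band_power(welch_psd(ep, window_s = 1), list(band_definition("a", 2, 20)))
  ep2 <- ep; ep2$epochs <- ep$epochs * 2
  bp2 <- band_power(welch_psd(ep2, window_s = 1), list(band_definition("a", 2, 20)))
  expect_equal(bp2$values, 4 * bp1$values, tolerance = 1e-12)

  perm <- ep; perm$epochs <- ep$epochs[c(4, 1, 6, 3, 2, 5), , , drop = FALSE]
  bp3 <- band_power(welch_psd(perm, window_s = 1), list(band_definition("a", 2, 20)))
  expect_equal(bp3$values, bp1$values, tolerance = 1e-12)
})

test_that("per-epoch band power matches whole-set averaging structure", {
  set.seed(3)
  ep <- noise_epochs(4, n_channels = 2, epoch_s = 2, fs = 128)
  arr <- epoch_band_power(ep, list(band_definition("a", 2, 20)),
                          window_s = 1, log10 = FALSE)
  expect_equal(dim(arr), c(4, 2, 1))
  one <- ep; one$epochs <- ep$epochs[2, , , drop = FALSE]
  bp <- band_power(welch_psd(one, window_s = 1), list(band_definition("a", 2, 20)))
  expect_equal(arr[2, , 1], bp$values[, 1], tolerance = 1e-12)
})
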