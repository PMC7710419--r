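test_that("average re-referencing zeroes the channel mean and is idempotent", {
  rec <- new_recording(matrix(c(1, 3), nrow = 2, ncol = 1), fs = 1,
                       channel_labels = c("a", "b"))
  out <- rereference_average(rec)
  expect_equal(out$data[, 1], c(a = -1, b = 1))

  set.seed(1)
  rec16 <- new_recording(matrix(rnorm(16 * 1000, sd = 10), 16), fs = 256)
  ref <- rereference_average(rec16)
  expect_lt(max(abs(colMeans(ref$data))), 1e-9)
  expect_equal(rereference_average(ref)$data, ref$data)

  expect_error(rereference_average(new_recording(matrix(1, 1, 10), 256)),
               "at least 2 channels")
})

test_that("band-pass keeps 10 Hz, removes DC, 0.2 Hz and 60 Hz", {
  fs <- 256
  t <- seq(0, 40 - 1 / fs, by = 1 / fs)
  mk <- function(x) new_recording(rbind(x, x), fs)
  rms <- function(x) sqrt(mean(x^2))
  inner <- (5 * fs):(35 * fs)   # avoid filter edge transients

  s10 <- sin(2 * pi * 10 * t)
  out10 <- bandpass(mk(s10))$data[1, ]
  expect_lt(abs(rms(out10[inner]) / rms(s10[inner]) - 1), 0.05)

  s60 <- sin(2 * pi * 60 * t)
  out60 <- bandpass(mk(s60))$data[1, ]
  expect_lt(rms(out60[inner]) / rms(s60[inner]), 0.10)

  s02 <- sin(2 * pi * 0.2 * t)
  out02 <- bandpass(mk(s02))$data[1, ]
  expect_lt(rms(out02[inner]) / rms(s02[inner]), 10^(-20 / 20))  # >= 20 dB down

  dc <- rep(50, length(t))
  outdc <- bandpass(mk(dc))$data[1, ]
  expect_lt(abs(mean(outdc[inner])), 0.5)

  expect_error(bandpass(mk(s10), low = 50, high = 45), "band edges")
  expect_error(bandpass(mk(s10), low = 1, high = 200), "band edges")
})

test_that("segmentation follows the floor rule with exact epoch sizes", {
  fs <- 256
  rec600 <- new_recording(matrix(rnorm(16 * 600 * fs), 16), fs)
  ep <- segment_epochs(rec600)
  expect_equal(dim(ep$epochs), c(100, 16, 1536))

  rec601 <- new_recording(matrix(rnorm(2 * 601 * fs), 2), fs)
  expect_equal(dim(segment_epochs(rec601)$epochs)[1], 100)

  rec5 <- new_recording(matrix(rnorm(2 * 5 * fs), 2), fs)
  expect_error(segment_epochs(rec5), "shorter than one epoch")

  # epochs tile the retained part of the recording exactly
  expect_equal(as.vector(ep$epochs[3, , ]),
               as.vector(rec600$data[, (2 * 1536 + 1):(3 * 1536)]))
})

test_that("artifact rejection uses strict |x| > threshold on any channel", {
  spw <- 6 * 4
  arr <- array(0, c(3, 2, spw))
  arr[1, 2, 5] <- 81    # rejected
  arr[2, 1, 1] <- 80    # boundary: retained under strict rule
  arr[3, , ] <- 79      # retained
  ep <- new_epoch_set(arr, 6, 4, c("a", "b"))

  out <- reject_artifacts(ep)
  expect_equal(out$retained_mask, c(FALSE, TRUE, TRUE))
  expect_equal(dim(out$epochs)[1], 2)

  out_inc <- reject_artifacts(ep, inclusive = TRUE)
  expect_equal(out_inc$retained_mask, c(FALSE, FALSE, TRUE))

  arr_bad <- array(100, c(2, 2, spw))
  expect_error(reject_artifacts(new_epoch_set(arr_bad, 6, 4, c("a", "b"))),
               "all epochs rejected")
  expect_error(reject_artifacts(ep, threshold = 0), "threshold")
})

test_that("segmentation plus rejection conserves the sample budget", {
  fs <- 128
  n <- 601 * fs
  rec <- new_recording(matrix(rnorm(2 * n), 2), fs)
  ep <- segment_epochs(rec)
  rej <- reject_artifacts(ep, threshold = 3)  # rejects some epochs
  spw <- dim(ep$epochs)[3]
  retained <- sum(rej$retained_mask) * spw
  rejected <- sum(!rej$retained_mask) * spw
  remainder <- n - length(ep$retained_mask) * spw
  expect_equal(retained + rejected + remainder, n)
})
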