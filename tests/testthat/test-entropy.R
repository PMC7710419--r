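test_that("fuzzy entropy equals the naive double-loop reference", {
  set.seed(101)
  for (i in 1:20) {
    m <- sample(1:3, 1)
    n <- sample(50:200, 1)
    x <- rnorm(n)
    got <- fuzzy_entropy(x, fuzzyen_params(m = m))
    want <- fuzzyen_oracle(x, m, 0.2 * sd(x))
    expect_equal(got, want, tolerance = 1e-12)
  }
})

test_that("fuzzy entropy is exactly scale- and offset-invariant", {
  set.seed(5)
  x <- rnorm(300)
  base <- fuzzy_entropy(x)
  # invariant by construction; tolerance covers float roundoff in the
  # baseline-removal arithmetic only
  expect_equal(fuzzy_entropy(2 * x + 5), base, tolerance = 1e-9)
  expect_equal(fuzzy_entropy(0.001 * x - 42), base, tolerance = 1e-9)
})

test_that("degenerate inputs are handled as defined", {
  expect_warning(v <- fuzzy_entropy(rep(3, 100)), "constant")
  expect_identical(v, 0)
  expect_error(fuzzy_entropy(c(1, 2, 3), fuzzyen_params(m = 2)), "longer")
  expect_error(fuzzyen_params(r = 0), "r must be")
  expect_error(fuzzyen_params(m = 0), "m must be")
})

test_that("entropy is non-increasing in the tolerance r", {
  set.seed(9)
  for (i in 1:5) {
    x <- rnorm(400)
    vals <- sapply(c(0.1, 0.2, 0.4),
                   function(r) fuzzy_entropy(x, fuzzyen_params(r = r)))
    expect_true(all(diff(vals) <= 0))
  }
})

test_that("white noise is more entropic than a matched sinusoid", {
  set.seed(13)
  fs <- 256
  t <- seq(0, 6 - 1 / fs, by = 1 / fs)
  s <- sqrt(2) * sin(2 * pi * 10 * t)   # unit variance
  e_sin <- fuzzy_entropy(s)
  wins <- sapply(1:10, function(i) fuzzy_entropy(rnorm(1536)) > e_sin)
  expect_true(all(wins))
})

test_that("epoch entropy reduces to single-signal entropy and averages epochs", {
  set.seed(21)
  fs <- 64
  x <- rnorm(2 * fs)
  one <- new_epoch_set(array(x, c(1, 1, length(x))), 2, fs, "ch1")
  expect_equal(epoch_entropy(one)$values[["ch1"]], fuzzy_entropy(x))

  # identical epochs: mean equals the single-epoch value
  arr <- array(rep(x, each = 3), c(3, 1, length(x)))
  for (e in 1:3) arr[e, 1, ] <- x
  same <- new_epoch_set(arr, 2, fs, "ch1")
  expect_equal(epoch_entropy(same)$values[["ch1"]], fuzzy_entropy(x))
  expect_equal(dim(epoch_entropy(same)$per_epoch), c(3, 1))
})

test_that("band-limited entropy decimates to a band-appropriate rate", {
  set.seed(31)
  fs <- 256
  arr <- array(rnorm(2 * 2 * 6 * fs), c(2, 2, 6 * fs))
  ep <- new_epoch_set(arr, 6, fs, c("a", "b"))
  delta <- band_definition("delta", 1, 4)
  # decimated series: 1536 / 16 = 96 samples; entropy must be finite
  en <- epoch_entropy(ep, band = delta)
  expect_true(all(is.finite(en$values)))
  # the same filtered signal undecimated saturates toward zero entropy
  en_full <- epoch_entropy(ep, band = delta, decimate = FALSE)
  expect_true(all(en_full$values < en$values))
})
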