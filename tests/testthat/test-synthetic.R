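# Short-duration configs keep the generator tests fast; the acceptance
# suite exercises the full 600-s / 100-epoch study conditions.

test_that("generation is a pure function of (config, state, seizure index)", {
  cfg <- synth_config(duration = 12, seed = 77)
  a <- generate_recording(cfg, "pre", 1)
  b <- generate_recording(cfg, "pre", 1)
  expect_identical(a$data, b$data)
  d <- generate_recording(cfg, "post", 1)
  expect_false(identical(a$data, d$data))
  # the ambient RNG stream is left untouched
  set.seed(99); x1 <- rnorm(3)
  set.seed(99); invisible(generate_recording(cfg, "pre", 1)); x2 <- rnorm(3)
  expect_identical(x1, x2)
})

test_that("per-band signal variance tracks the configured band powers", {
  cfg <- synth_config(duration = 600, noise_sd = 0, seed = 88)
  rec <- generate_recording(cfg, "pre", 1)
  bp <- band_power(welch_psd(segment_epochs(rec)))
  target <- c(delta = 50, theta = 25, alpha = 30, beta = 15, low_gamma = 5)
  rel <- colMeans(bp$values)[names(target)] / target
  expect_true(all(abs(rel - 1) < 0.1))
})

test_that("a planted delta power ratio is realized within tolerance", {
  eff <- pre_post_effect(delta_power_ratio = 2)
  cfg <- synth_config(duration = 600, effect = eff, seed = 21)
  pre <- generate_recording(cfg, "pre", 1)
  post <- generate_recording(cfg, "post", 1)
  r <- band_power(welch_psd(segment_epochs(post)))$values[, "delta"] /
    band_power(welch_psd(segment_epochs(pre)))$values[, "delta"]
  expect_lt(abs(mean(r) - 2), 0.2)
})

test_that("near-unity coupling with no noise drives coherence toward 1", {
  K <- matrix(c(0, 0.99, 0.99, 0), 2, 2)
  cfg <- synth_config(n_channels = 2, duration = 120, noise_sd = 0,
                      coupling = list(delta = K), seed = 31)
  ep <- segment_epochs(generate_recording(cfg, "pre", 1))
  cm <- coherence_matrix(ep, default_bands()$delta)
  expect_gt(cm$C[1, 2], 0.9)
})

test_that("infeasible coupling requests fail with the offending pair named", {
  K <- matrix(0, 16, 16); K[1, 2] <- K[2, 1] <- 0.5
  cfg <- synth_config(coupling = list(low_gamma = K), duration = 12, seed = 1)
  expect_error(generate_recording(cfg, "pre", 1), "infeasible coupling.*pair \\(1, 2\\)")

  # a channel whose pairs jointly exceed unit shared power
  K2 <- matrix(0, 16, 16)
  K2[1, 2:5] <- K2[2:5, 1] <- 0.4
  cfg2 <- synth_config(coupling = list(delta = K2), duration = 12, seed = 1)
  expect_error(generate_recording(cfg2, "pre", 1), "total shared power")
})

test_that("config invariants are validated", {
  expect_error(synth_config(fs = 80), "twice the highest band edge")
  expect_error(synth_config(duration = 1.0001), "integer sample count")
  K <- matrix(0.2, 16, 16)            # nonzero diagonal
  expect_error(synth_config(coupling = K), "zero diagonal")
  K2 <- matrix(0, 16, 16); K2[1, 2] <- 0.3
  expect_error(synth_config(coupling = K2), "symmetric")
  K3 <- matrix(0, 16, 16); K3[1, 2] <- K3[2, 1] <- 1
  expect_error(synth_config(coupling = K3), "\\[0, 1\\)")
  expect_error(pre_post_effect(delta_power_ratio = 0), "> 0")
  expect_error(pre_post_effect(entropy_shift = -1), "1 \\+ shift")
})

test_that("artifact injection plants an exact, recoverable window set", {
  cfg <- synth_config(duration = 600, seed = 60)
  rec <- generate_recording(cfg, "pre", 1)

  out0 <- inject_artifacts(rec, rate = 0, seed = 1)
  expect_identical(out0$recording$data, rec$data)
  expect_length(out0$windows, 0)

  out <- inject_artifacts(rec, rate = 0.1, amplitude = 150, seed = 2)
  expect_length(out$windows, 10)
  ep <- preprocess(out$recording)
  expect_equal(which(!ep$retained_mask), out$windows)

  expect_error(inject_artifacts(rec, rate = 1.5, seed = 1), "rate")
  expect_error(inject_artifacts(rec, rate = 0.1, amplitude = 79, seed = 1),
               "exceed 80")
})

test_that("seizure series are labeled in temporal order and validated", {
  cfg <- synth_config(duration = 12, seed = 5)
  recs <- generate_seizure_series(cfg, 4)
  expect_length(recs, 8)
  expect_equal(names(recs), c("1-pre", "1-post", "2-pre", "2-post",
                              "3-pre", "3-post", "4-pre", "4-post"))
  expect_error(generate_seizure_series(cfg, 1), ">= 2")

  # a trend that pushes coupling below zero must fail loudly
  K <- matrix(0, 16, 16); K[1, 2] <- K[2, 1] <- 0.05
  eff <- pre_post_effect(edge_shifts = list(delta = -0.04 * (K > 0)),
                         seizure_trend = 1)
  cfg2 <- synth_config(duration = 12, coupling = list(delta = K),
                       effect = eff, seed = 5)
  expect_error(generate_seizure_series(cfg2, 4), "\\[0, 1\\)")
})
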