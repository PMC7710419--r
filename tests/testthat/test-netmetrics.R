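test_that("complete unit-weight graphs give CPL = 1 and CC = 1", {
  for (n in c(3, 5, 16)) {
    C <- matrix(1, n, n); diag(C) <- 0
    expect_equal(characteristic_path_length(C), 1)
    expect_equal(clustering_coefficient(C, "printed"), 1)
    expect_equal(clustering_coefficient(C, "standard"), 1)
  }
})

test_that("the 3-node path example reproduces hand-computed shortest paths", {
  C <- matrix(0, 3, 3)
  C[1, 2] <- C[2, 1] <- 0.5
  C[2, 3] <- C[3, 2] <- 0.5
  # lengths 2 and 2; d(A,C) = 4; CPL = (2 + 2 + 4) / 3
  expect_equal(characteristic_path_length(C), 8 / 3)
  expect_equal(characteristic_path_length(C), fw_cpl_oracle(C))
})

test_that("CPL matches the Floyd-Warshall oracle on random graphs", {
  set.seed(20)
  for (i in 1:20) {
    C <- random_conn(16, density = runif(1, 0.5, 1))
    got <- tryCatch(characteristic_path_length(C), error = function(e) NA)
    if (is.na(got)) next   # disconnected draw
    expect_equal(got, fw_cpl_oracle(C), tolerance = 1e-12)
  }
})

test_that("both clustering variants match the triple-loop oracle", {
  set.seed(21)
  for (i in 1:20) {
    C <- random_conn(16, density = 0.8)
    expect_equal(suppressWarnings(clustering_coefficient(C, "printed")),
                 cc_oracle(C, "printed"), tolerance = 1e-12)
    expect_equal(clustering_coefficient(C, "standard"),
                 cc_oracle(C, "standard"), tolerance = 1e-12)
  }
})

test_that("degenerate graphs are handled as documented", {
  empty <- matrix(0, 4, 4)
  expect_equal(clustering_coefficient(empty, "printed"), 0)
  expect_equal(clustering_coefficient(empty, "standard"), 0)
  expect_error(characteristic_path_length(empty), "disconnected")
  eff <- characteristic_path_length(empty, disconnected = "efficiency")
  expect_true(is.finite(attr(eff, "efficiency")))

  # strength <= 1 under the printed variant: contributing nodes zeroed
  C <- matrix(0, 3, 3)
  C[1, 2] <- C[2, 1] <- C[1, 3] <- C[3, 1] <- C[2, 3] <- C[3, 2] <- 0.3
  expect_warning(v <- clustering_coefficient(C, "printed"), "strength")
  expect_equal(v, 0)
  expect_gt(clustering_coefficient(C, "standard"), 0)
})

test_that("metrics are invariant to node relabeling", {
  set.seed(22)
  C <- random_conn(10, density = 1)
  p <- sample(10)
  Cp <- C[p, p]
  expect_equal(characteristic_path_length(Cp), characteristic_path_length(C),
               tolerance = 1e-12)
  for (v in c("printed", "standard")) {
    expect_equal(suppressWarnings(clustering_coefficient(Cp, v)),
                 suppressWarnings(clustering_coefficient(C, v)),
                 tolerance = 1e-12)
  }
})

test_that("uniform weight scaling behaves as documented per variant", {
  set.seed(23)
  C <- random_conn(8, density = 1, max_w = 0.5)
  a <- 0.5
  expect_equal(characteristic_path_length(a * C),
               characteristic_path_length(C) / a, tolerance = 1e-12)
  # standard variant scales linearly in the weights
  expect_equal(clustering_coefficient(a * C, "standard"),
               a * clustering_coefficient(C, "standard"), tolerance = 1e-12)
  # printed variant is NOT scale-invariant nor linear: strengths rescale too
  cp1 <- suppressWarnings(clustering_coefficient(C, "printed"))
  cpa <- suppressWarnings(clustering_coefficient(a * C, "printed"))
  expect_false(isTRUE(all.equal(cpa, cp1)))
  expect_false(isTRUE(all.equal(cpa, a * cp1)))
})

test_that("band_metrics returns one row per band", {
  set.seed(24)
  mats <- list(delta = random_conn(6, density = 1),
               theta = random_conn(6, density = 1))
  bands <- list(band_definition("delta", 1, 4), band_definition("theta", 4, 8))
  out <- suppressWarnings(band_metrics(mats, bands))
  expect_equal(nrow(out), 2)
  expect_equal(out$band, c("delta", "theta"))
  expect_true(all(out$cpl > 0))
})

test_that("proportional thresholding keeps the strongest edges only", {
  C <- matrix(0, 4, 4)
  C[1, 2] <- C[2, 1] <- 0.9
  C[2, 3] <- C[3, 2] <- 0.5
  C[3, 4] <- C[4, 3] <- 0.1
  Ct <- proportional_threshold(C, 2 / 3)
  expect_equal(sum(Ct[upper.tri(Ct)] > 0), 2)
  expect_equal(Ct[1, 2], 0.9)
  expect_equal(Ct[3, 4], 0)
  expect_equal(proportional_threshold(C, 1), C)
  expect_error(proportional_threshold(C, 0), "density")
})

test_that("stronger global coupling lowers CPL and raises clustering", {
  delta <- default_bands()$delta
  # two-tier ring: adjacent k, next-adjacent k/3 (keeps per-channel shared
  # power feasible at the strong setting)
  ring <- function(k) {
    K <- matrix(0, 16, 16)
    for (i in 1:16) for (d in 1:2) {
      j <- ((i + d - 1) %% 16) + 1
      K[i, j] <- K[j, i] <- k / c(1, 3)[d]
    }
    K
  }
  m <- sapply(c(weak = 0.03, strong = 0.09), function(k) {
    rowMeans(sapply(1:4, function(s) {
      cfg <- synth_config(duration = 60, coupling = list(delta = ring(k)),
                          seed = 500 + s)
      C <- coherence_matrix(segment_epochs(generate_recording(cfg, "pre", 1)),
                            delta)
      c(cpl = characteristic_path_length(C),
        cc = clustering_coefficient(C, "standard"))
    }))
  })
  expect_lt(m["cpl", "strong"], m["cpl", "weak"])
  expect_gt(m["cc", "strong"], m["cc", "weak"])
})
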