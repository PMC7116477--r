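test_that("companion-matrix stability check matches analytic root moduli", {
  expect_true(is_stable(mvar_model(list(matrix(0.5)), matrix(1))))
  expect_false(is_stable(mvar_model(list(matrix(1.0)), matrix(1))))
  # roots of z^2 - z + 0.9: modulus sqrt(0.9) < 1
  expect_true(is_stable(mvar_model(list(matrix(1.0), matrix(-0.9)), matrix(1))))
  expect_false(is_stable(mvar_model(list(matrix(1.0), matrix(-1.1)), matrix(1))))
})

test_that("simulation is seeded, stationary and matches the AR(1) variance law", {
  m <- mvar_model(list(matrix(0.9)), matrix(1))
  x1 <- simulate_mvar(m, 1e5, seed = 7)
  x2 <- simulate_mvar(m, 1e5, seed = 7)
  expect_identical(x1$data, x2$data)
  expect_equal(var(x1$data[1, ]), 1 / (1 - 0.81), tolerance = 0.02)
  # pure innovation: lag-1 autocorrelation vanishes
  w <- simulate_mvar(mvar_model(list(matrix(0, 2, 2)), diag(2)), 5e4, seed = 8)
  ac <- acf(w$data[1, ], lag.max = 1, plot = FALSE)$acf[2]
  expect_lt(abs(ac), 0.02)
  expect_error(simulate_mvar(mvar_model(list(matrix(1.0)), matrix(1)), 100, seed = 1),
               "not stable")
})

test_that("random graphs are valid, saturate, and sample ordered pairs uniformly", {
  g <- random_graph(3, 3, seed = 1)
  expect_equal(nrow(g$edges), 3)
  expect_false(anyDuplicated(g$edges[, c("from", "to")]) > 0)
  expect_true(all(g$edges$lag %in% 1:3))
  g6 <- random_graph(3, 6, seed = 2)
  expect_equal(sum(adjacency(g6)), 6)
  expect_error(random_graph(3, 7, seed = 3), "exceeds")
  # uniformity over the 6 ordered pairs, 1e4 single-edge draws
  draws <- vapply(seq_len(1e4), function(k) {
    e <- random_graph(3, 1, seed = k)$edges
    (e$from - 1) * 3 + e$to
  }, 0)
  counts <- table(draws)
  expect_length(counts, 6)
  p <- 1 / 6
  band <- 3 * sqrt(1e4 * p * (1 - p))
  expect_true(all(abs(counts - 1e4 * p) < band))
})

test_that("periodic model builder yields stable resonators peaking near the target", {
  for (s in 1:5) {
    g <- random_graph(3, sample(1:3, 1), seed = 40 + s)
    m <- build_periodic_model(g)
    expect_true(is_stable(m))
  }
  m3 <- model_common_drive()
  x <- simulate_mvar(m3, 3e4, seed = 12)
  p <- psd(spectral_matrix(x, 256), 1)
  pk <- p$freq[which.max(p$power)]
  expect_gt(pk, 45)
  expect_lt(pk, 65)
  # no edges: block-diagonal model, channels pairwise incoherent
  m0 <- build_periodic_model(directed_graph(2))
  x0 <- simulate_mvar(m0, 3e4, seed = 13)
  co <- coherence(spectral_matrix(x0, 256), 1, 2)
  expect_lt(mean(co$coherence, na.rm = TRUE), 0.05)
})

test_that("observation model z-standardizes, mixes and degrades as specified", {
  m <- model_unidir()
  x <- simulate_mvar(m, 2e4, seed = 14)
  # identity observation: per-channel z-score, correlation 1 with input
  y0 <- observe(x, observation_spec(noise_scale = 0), seed = 1)
  expect_equal(unname(rowMeans(y0$data)), c(0, 0), tolerance = 1e-12)
  expect_equal(unname(apply(y0$data, 1, sd)), c(1, 1), tolerance = 1e-12)
  expect_equal(cor(y0$data[1, ], x$data[1, ]), 1, tolerance = 1e-12)
  # heavy noise: correlation with input collapses
  yb <- observe(x, observation_spec(noise_scale = 50), seed = 2)
  expect_lt(abs(cor(yb$data[1, ], x$data[1, ])), 0.1)
  expect_error(observation_spec(mixing = matrix(c(2, 0, 0, 1), 2)), "unit diagonal")
})

test_that("narrowband SNR follows the decibel log-ratio definition", {
  f <- seq(0, 100, by = 1)
  mk <- function(p) data.frame(freq = f, power = rep(p, length(f)))
  expect_equal(narrowband_snr_db(mk(1), mk(1), c(40, 60)), 0)
  expect_equal(narrowband_snr_db(mk(1), mk(10), c(40, 60)), -10)
  expect_equal(narrowband_snr_db(mk(100), mk(1), c(40, 60)), 20)
  expect_identical(narrowband_snr_db(mk(1), mk(0), c(40, 60)), Inf)
})

test_that("noise-scale solver round-trips the target SNR and is monotone", {
  m <- model_common_drive()
  x <- simulate_mvar(m, 5e4, seed = 15)
  band <- c(50, 60)
  expect_identical(lambda_for_snr(x, 1, Inf, band), 0)
  lams <- vapply(c(10, 0, -10), function(s) lambda_for_snr(x, 1, s, band), 0)
  expect_true(all(diff(lams) > 0))  # lower SNR needs more noise
  # round trip: measure achieved SNR from the component spectra
  for (target in c(5, -5)) {
    lam <- lambda_for_snr(x, 1, target, band)
    z <- timeseries(matrix(scale(x$data[1, ])[, 1], 1), fs = x$fs)
    set.seed(16)
    nz <- timeseries(matrix(rnorm(ncol(x$data)) * lam, 1), fs = x$fs)
    got <- narrowband_snr_db(psd(spectral_matrix(z, 256), 1),
                             psd(spectral_matrix(nz, 256), 1), band)
    expect_equal(got, target, tolerance = 0.5)
  }
})

test_that("mixing calibration hits the requested shared variance", {
  m <- model_common_drive()
  x <- simulate_mvar(m, 3e4, seed = 17)
  for (sv in c(0.2, 0.45)) {
    L <- calibrate_mixing(x, sv)
    expect_equal(unname(diag(L)), rep(1, 3))
    cc <- cor(t(L %*% x$data))
    expect_equal(mean(cc[upper.tri(cc)]^2), sv, tolerance = 0.01)
  }
})
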