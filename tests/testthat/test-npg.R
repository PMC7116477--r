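test_that("Wilson factorization recovers the innovation covariance of known models", {
  for (build in list(model_unidir, model_common_drive)) {
    m <- build()
    St <- mvar_spectrum(m, fs = 200, seg_len = 256)
    f <- wilson_factorize(St)
    expect_lt(max(abs(f$Sigma - m$noise_cov)), 0.02)   # within 2%
    # H is normalized to identity at lag zero: Sigma symmetric PD
    expect_equal(f$Sigma, t(f$Sigma), tolerance = 1e-12)
    expect_true(all(eigen(f$Sigma, only.values = TRUE)$values > 0))
  }
})

test_that("factorization reconstructs the spectrum and keeps diagonal structure", {
  # gentle diagonal model: high-accuracy reconstruction, H and Sigma diagonal
  m <- mvar_model(list(diag(c(0.5, 0.3))), diag(2))
  St <- mvar_spectrum(m, fs = 200, seg_len = 128)
  f <- wilson_factorize(St)
  expect_lt(f$resid, 1e-8)
  expect_lt(max(abs(f$Sigma[upper.tri(f$Sigma)])), 1e-8)
  expect_lt(max(Mod(f$H[1, 2, ])), 1e-6)
  expect_lt(max(Mod(f$H[2, 1, ])), 1e-6)
  # explicit reconstruction check H Sigma H* = S (per-bin units)
  for (k in c(1, 20, 65)) {
    rec <- f$H[, , k] %*% f$Sigma %*% Conj(t(f$H[, , k]))
    expect_lt(max(Mod(rec - St$S[, , k] * 200)), 1e-8)
  }
})

test_that("pairwise NPG matches the parametric Geweke oracle", {
  m <- model_unidir()
  St <- mvar_spectrum(m, fs = 200, seg_len = 1024)
  g <- pairwise_npg(St, 1, 2, max_iter = 3000)
  expect_lt(max(abs(g$granger$forward - parametric_geweke(m, 1024, 1, 2))), 0.05)
  expect_lt(max(abs(g$granger$reverse - pmax(parametric_geweke(m, 1024, 2, 1), 0))), 0.05)
  # 3-node model, X -> Z pair
  m3 <- model_common_drive()
  St3 <- mvar_spectrum(m3, fs = 200, seg_len = 1024)
  g3 <- pairwise_npg(St3, 1, 3, max_iter = 3000)
  expect_lt(max(abs(g3$granger$forward - parametric_geweke(m3, 1024, 1, 3))), 0.05)
})

test_that("directional spectra identify the coupling and vanish without it", {
  m <- model_unidir()
  x <- simulate_mvar(m, 5e4, seed = 501)
  S <- spectral_matrix(x, 256)
  g <- pairwise_npg(S, 1, 2)
  pk <- which.max(g$granger$forward[-1]) + 1L
  expect_gt(S$freqs[pk], 40)
  expect_lt(S$freqs[pk], 70)
  expect_gt(max(g$granger$forward[-1]), 0.3)
  expect_lt(max(g$granger$reverse[-1]), 0.15)
  expect_true(all(g$granger$forward >= 0))
  w <- white_ts(2, 5e4, seed = 502)
  gw <- pairwise_npg(spectral_matrix(w, 256), 1, 2)
  expect_lt(max(gw$granger$forward), 0.1)
  # invariance to channel ordering of the input matrix
  xr <- timeseries(x$data[2:1, ], fs = 200)
  gr <- pairwise_npg(spectral_matrix(xr, 256), 2, 1)
  expect_equal(gr$granger$forward, g$granger$forward, tolerance = 1e-10)
})

test_that("multivariate NPG reduces to pairwise for two channels", {
  m <- model_unidir()
  St <- mvar_spectrum(m, fs = 200, seg_len = 256)
  pw <- pairwise_npg(St, 1, 2)
  for (meth in c("conditional", "full")) {
    mv <- multivariate_npg(St, method = meth)
    expect_lt(max(abs(mv$granger[1, 2, ] - pw$granger$forward)), 1e-8)
    expect_lt(max(abs(mv$granger[2, 1, ] - pw$granger$reverse)), 1e-8)
  }
})

test_that("conditional multivariate NPG nulls a fully observed relay", {
  m <- model_serial_gentle()      # X -> Z -> Y
  St <- mvar_spectrum(m, fs = 200, seg_len = 512)
  mv <- multivariate_npg(St, method = "conditional", max_iter = 2000)
  expect_lt(max(mv$granger[1, 2, ]), 1e-6)       # X -> Y given Z vanishes
  expect_gt(max(mv$granger[1, 3, ]), 0.2)        # the true edges remain
  expect_gt(max(mv$granger[3, 2, ]), 0.2)
})

test_that("both multivariate forms suppress lagged common drive", {
  m <- model_common_drive()
  x <- simulate_mvar(m, 5e4, seed = 503)
  S <- spectral_matrix(x, 256)
  spurious_pw <- max(pairwise_npg(S, 2, 3)$granger$forward[-1])
  expect_gt(spurious_pw, 0.1)                    # pairwise sees spurious Y -> Z
  for (meth in c("conditional", "full")) {
    mv <- multivariate_npg(S, method = meth)
    expect_lt(max(mv$granger[2, 3, -1]), 0.5 * spurious_pw)
  }
})
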