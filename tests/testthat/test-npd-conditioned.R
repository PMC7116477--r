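test_that("partialization removes exactly the reference channel's linear contribution", {
  # independent reference: partial spectra equal the originals
  m <- model_unidir()
  x <- simulate_mvar(m, 2e4, seed = 401)
  set.seed(402)
  x3 <- timeseries(rbind(x$data, rnorm(ncol(x$data))), fs = 200)
  S <- spectral_matrix(x3, 256)
  Sp <- partialize(S, 3)
  expect_equal(Sp$channel_map, c(1, 2))
  expect_equal(Re(Sp$S[1, 1, ]), Re(S$S[1, 1, ]), tolerance = 0.05)
  expect_lt(max(Mod(Sp$S[2, 1, ] - S$S[2, 1, ])) / max(Mod(S$S[2, 1, ])), 0.1)
  # exact instantaneous copy: conditioned autospectrum collapses
  dup <- timeseries(rbind(x$data[1, ], x$data[2, ], x$data[2, ]), fs = 200)
  Sd <- spectral_matrix(dup, 256)
  Spd <- partialize(Sd, 3)
  expect_lt(max(Re(Spd$S[2, 2, ])) / max(Re(Sd$S[2, 2, ])), 1e-10)
})

test_that("a fully observed serial chain has zero partial coherence (exact spectrum)", {
  m <- model_serial_gentle()       # X -> Z -> Y
  St <- mvar_spectrum(m, fs = 200, seg_len = 256)
  pc <- coherence(partialize(St, 3), 1, 2)$coherence
  expect_lt(max(pc, na.rm = TRUE), 1e-10)
  # and the conditioned NPD components vanish with it
  dc <- conditioned_npd(St, 1, 2, ref = 3)
  expect_lt(max(dc$forward + dc$reverse + dc$zero), 1e-10)
})

test_that("conditioning on the common source removes spurious directionality", {
  m <- model_common_drive()        # X -> Y lag 2, X -> Z lag 3
  x <- simulate_mvar(m, 5e4, seed = 403)
  S <- spectral_matrix(x, 256)
  d_yz <- npd_decompose(S, 2, 3)   # spurious Y -> Z from lagged common drive
  dc_yz <- conditioned_npd(S, 2, 3, ref = 1)
  expect_gt(max(d_yz$forward[-1]), 0.2)
  expect_lt(max(dc_yz$forward[-1]), 0.1)
  # conditioning on an irrelevant noise channel changes nothing material
  set.seed(404)
  x4 <- timeseries(rbind(x$data, rnorm(ncol(x$data))), fs = 200)
  S4 <- spectral_matrix(x4, 256)
  d12 <- npd_decompose(S4, 1, 2)
  dc12 <- conditioned_npd(S4, 1, 2, ref = 4)
  expect_equal(max(dc12$forward[-1]), max(d12$forward[-1]), tolerance = 0.1)
})

test_that("feedforward conditioning attenuates partially and degrades with reference noise", {
  # X -> Y -> Z: conditioning on terminal Z attenuates X -> Y but not fully
  edges <- data.frame(from = c(1, 2), to = c(2, 3), lag = 2)
  m <- build_periodic_model(directed_graph(3, edges))
  x <- simulate_mvar(m, 5e4, seed = 405)
  S <- spectral_matrix(x, 256)
  un <- max(npd_decompose(S, 1, 2)$forward[-1])
  cond <- max(conditioned_npd(S, 1, 2, ref = 3)$forward[-1])
  expect_lt(cond, un)          # some attenuation
  expect_gt(cond, 0.05 * un)   # but never complete
  # attenuation shrinks as the reference observation gets noisier
  atten <- vapply(c(Inf, 0, -20), function(snr) {
    lam <- c(0, 0, lambda_for_snr(x, 3, snr, c(50, 60)))
    y <- observe(x, observation_spec(noise_scale = lam), seed = 406)
    Sy <- spectral_matrix(y, 256)
    max(npd_decompose(Sy, 1, 2)$forward[-1]) -
      max(conditioned_npd(Sy, 1, 2, ref = 3)$forward[-1])
  }, 0)
  expect_gt(atten[1], atten[3] - 0.05)   # monotone up to estimator noise
})
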