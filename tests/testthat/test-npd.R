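test_that("pre-whitening gives a unit diagonal and reproduces coherence exactly", {
  m <- model_common_drive()
  x <- simulate_mvar(m, 2e4, seed = 301)
  S <- spectral_matrix(x, 256)
  Fw <- prewhiten(S)
  for (i in 1:3) expect_lt(max(abs(Fw$Fw[i, i, ] - 1)), 1e-10)
  co <- coherence(S, 1, 2)$coherence
  expect_lt(max(abs(Mod(Fw$Fw[2, 1, ])^2 - co)), 1e-10)
  # whitening a white process changes nothing but scale
  w <- white_ts(2, 2e4, seed = 302)
  Sw <- spectral_matrix(w, 256)
  Fww <- prewhiten(Sw)
  expect_equal(Mod(Fww$Fw[2, 1, ])^2, coherence(Sw, 1, 2)$coherence, tolerance = 1e-12)
})

test_that("whitened lag correlation localizes delays and satisfies Parseval", {
  n <- 20000
  set.seed(303)
  s <- rnorm(n + 5)
  x <- timeseries(rbind(s[6:(n + 5)], s[1:n] + 0.05 * rnorm(n)), fs = 200)
  Fw <- prewhiten(spectral_matrix(x, 256))
  r <- lag_correlation(Fw, 1, 2)
  expect_equal(r$lag[which.max(abs(r$rho))], 5)
  # instantaneous mixing of independent channels: peak at zero lag
  set.seed(304)
  a <- rnorm(n); b <- rnorm(n)
  xm <- timeseries(rbind(a + 0.5 * b, b + 0.5 * a), fs = 200)
  rm_ <- lag_correlation(prewhiten(spectral_matrix(xm, 256)), 1, 2)
  expect_equal(rm_$lag[which.max(abs(rm_$rho))], 0)
  # discrete Parseval: sum of rho^2 = mean coherence over the two-sided grid
  fw <- Fw$Fw[2, 1, ]
  coh2 <- c(Mod(fw)^2, Mod(fw[128:2])^2)
  expect_equal(sum(r$rho^2), mean(coh2), tolerance = 1e-8)
})

test_that("the three components add up to coherence and swap under argument exchange", {
  for (seed in c(305, 306, 307)) {
    g <- random_graph(3, 2, seed = seed)
    m <- build_periodic_model(g)
    x <- simulate_mvar(m, 1e4, seed = seed)
    S <- spectral_matrix(x, 256)
    d <- npd_decompose(S, 1, 2)
    expect_lt(max(abs(d$forward + d$reverse + d$zero - d$coherence)), 1e-8)
    expect_true(all(d$forward >= 0) && all(d$reverse >= 0) && all(d$zero >= 0))
    # scalar components integrate the lag-domain energy
    expect_equal(sum(d$scalar), sum(d$rho$rho^2), tolerance = 1e-8)
    d2 <- npd_decompose(S, 2, 1)
    expect_equal(d$forward, d2$reverse, tolerance = 1e-12)
    expect_equal(d$reverse, d2$forward, tolerance = 1e-12)
    expect_equal(d$zero, d2$zero, tolerance = 1e-12)
  }
})

test_that("directional loading matches the generating mechanism", {
  # pure delay: forward component carries nearly all dependence
  n <- 30000
  set.seed(308)
  s <- rnorm(n + 4)
  x <- timeseries(rbind(s[5:(n + 4)], s[1:n] + 0.2 * rnorm(n)), fs = 200)
  d <- npd_decompose(spectral_matrix(x, 256), 1, 2)
  expect_gte(d$scalar["forward"] / sum(d$scalar), 0.95)
  # zero-lag mixing of independent channels loads the zero-lag component
  set.seed(309)
  a <- rnorm(n); b <- rnorm(n)
  xm <- timeseries(rbind(a + 0.6 * b, b + 0.6 * a), fs = 200)
  dm <- npd_decompose(spectral_matrix(xm, 256), 1, 2)
  expect_gte(dm$scalar["zero"] / sum(dm$scalar), 0.95)
  # independent channels: everything near zero
  w <- white_ts(2, 3e4, seed = 310)
  dw <- npd_decompose(spectral_matrix(w, 256), 1, 2)
  expect_lt(max(dw$forward), 0.1)
})

test_that("unidirectional coupling puts the coherence into the forward component", {
  m <- model_unidir()
  x <- simulate_mvar(m, 5e4, seed = 311)
  S <- spectral_matrix(x, 256)
  d <- npd_decompose(S, 1, 2)
  pk <- which.max(d$coherence[-1]) + 1L
  expect_gt(d$coherence[pk], 0.4)
  expect_equal(d$forward[pk], d$coherence[pk], tolerance = 0.1)
  expect_lt(max(d$reverse[-1]), 0.1)
})

test_that("a symmetric reciprocal model yields approximately symmetric estimates", {
  m <- model_reciprocal()
  x <- simulate_mvar(m, 5e4, seed = 312)
  d <- npd_decompose(spectral_matrix(x, 256), 1, 2)
  expect_lt(abs(max(d$forward[-1]) - max(d$reverse[-1])), 0.1)
})
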