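# Shared fixtures: small models and independent oracles, built in code.

# 2-node unidirectional model: X (1) drives Y (2) at lag 2.
model_unidir <- function(...) {
  build_periodic_model(directed_graph(2, data.frame(from = 1, to = 2, lag = 2)), ...)
}

# 3-node common-drive model: X -> Y at lag 2, X -> Z at lag 3.
model_common_drive <- function(...) {
  build_periodic_model(
    directed_graph(3, data.frame(from = c(1, 1), to = c(2, 3), lag = c(2, 3))), ...)
}

# 2-node symmetric reciprocal model (equal lags and couplings).
model_reciprocal <- function(...) {
  build_periodic_model(
    directed_graph(2, data.frame(from = c(1, 2), to = c(2, 1), lag = 2)), ...)
}

# Gentle serial chain X -> Z -> Y as plain AR(1) nodes; well-conditioned
# spectra for exact conditional-causality checks.
model_serial_gentle <- function() {
  A1 <- matrix(0, 3, 3)
  diag(A1) <- 0.5
  A1[3, 1] <- 0.4   # X -> Z
  A1[2, 3] <- 0.4   # Z -> Y
  mvar_model(list(A1))
}

white_ts <- function(n_ch = 2, T = 20000, fs = 200, seed = 99) {
  set.seed(seed)
  timeseries(matrix(rnorm(n_ch * T), n_ch), fs = fs)
}

# Independent parametric oracle: Geweke directional spectrum computed from
# the true MVAR coefficients (no spectral factorization involved).
parametric_geweke <- function(model, seg_len, x, y, fs = 200) {
  m <- seg_len %/% 2L
  out <- numeric(m + 1L)
  R <- model$noise_cov
  for (k in 0:m) {
    z <- exp(-1i * 2 * pi * k / seg_len)
    A <- diag(model$n_channels) + 0i
    for (i in seq_len(model$order)) A <- A - model$coeffs[[i]] * z^i
    H <- solve(A)
    Syy <- Re((H %*% R %*% Conj(t(H)))[y, y])
    Ht <- H[y, y] + H[y, x] * R[x, y] / R[y, y]
    out[k + 1L] <- log(Syy / (Mod(Ht)^2 * R[y, y]))
  }
  out
}
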