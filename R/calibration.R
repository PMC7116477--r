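# Confound-calibration sweeps and logistic curve summaries.

peak_of <- function(spec) max(spec[-1], na.rm = TRUE)  # DC excluded

#' Fit a logistic response curve by least squares
#'
#' Fits `y = A / (1 + exp(-kappa * (x - x0)))` with multi-start
#' Levenberg-Marquardt least squares. `kappa` carries units of 1/x (per dB
#' for SNR sweeps). Fits with `r_squared <= 0.95` are returned with
#' `below_threshold = TRUE` rather than an error; constant input is rejected
#' (the midpoint is undefined).
#'
#' @param x,y numeric vectors (>= 5 points).
#' @return An object of class `"logistic_fit"`: `maximum`, `x0`, `kappa`,
#'   `r_squared`, `fitted`, `below_threshold`.
#' @export
fit_logistic <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 5L, all(is.finite(x)), all(is.finite(y)))
  if (stats::sd(y) < 1e-12 * (abs(mean(y)) + 1))
    stop("constant response: logistic midpoint is undefined")
  A0 <- max(y)
  half <- A0 / 2
  x0_0 <- x[which.min(abs(y - half))]
  span <- diff(range(x))
  starts <- expand.grid(x0 = c(x0_0, stats::quantile(x, c(0.25, 0.5, 0.75))),
                        kappa = c(0.5, 2, 10) / span)
  best <- NULL
  for (s in seq_len(nrow(starts))) {
    fit <- tryCatch(
      minpack.lm::nlsLM(y ~ A / (1 + exp(-kappa * (x - x0))),
                        start = list(A = unname(A0), x0 = unname(starts$x0[s]),
                                     kappa = unname(starts$kappa[s])),
                        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (is.null(fit)) next
    rss <- sum(stats::residuals(fit)^2)
    if (is.null(best) || rss < best$rss) best <- list(fit = fit, rss = rss)
  }
  if (is.null(best)) stop("logistic fit did not converge from any start")
  cf <- stats::coef(best$fit)
  r2 <- 1 - best$rss / sum((y - mean(y))^2)
  structure(list(maximum = unname(cf["A"]), x0 = unname(cf["x0"]),
                 kappa = unname(cf["kappa"]), r_squared = r2,
                 fitted = stats::fitted(best$fit),
                 below_threshold = r2 <= 0.95),
            class = "logistic_fit")
}

#' @export
print.logistic_fit <- function(x, ...) {
  cat(sprintf("<logistic_fit> A = %.4g, x0 = %.4g, kappa = %.4g, R^2 = %.4f%s\n",
              x$maximum, x$x0, x$kappa, x$r_squared,
              if (x$below_threshold) " (below R^2 > 0.95 reporting threshold)" else ""))
  invisible(x)
}

#' Sweep symmetric signal-to-noise ratio
#'
#' Simulates the model once, then for each SNR level adds equal observation
#' noise to every channel (calibrated per channel to the target narrowband
#' SNR), and records the peak (over frequency, DC excluded) of coherence,
#' forward NPD and forward pairwise NPG for the requested pair. When
#' `n_surrogates > 0`, a P = `1 - percentile/100` phase-randomization
#' confidence limit (max-statistic pooling) is computed per condition for NPD
#' and NPG.
#'
#' @param model a stable [mvar_model()].
#' @param snr_grid_db numeric vector of target SNRs in dB (`Inf` = no noise).
#' @param seed integer seed.
#' @param pair length-2 channel indices (source, target); default c(1, 2).
#' @param band narrowband SNR accounting interval, Hz; default the 55 Hz
#'   spectral peak +/- 5 Hz.
#' @param n_samples,fs,seg_len simulation and estimation settings.
#' @param n_surrogates surrogate count per condition (0 = skip thresholds).
#' @param percentile surrogate percentile (default 99.9).
#' @return data.frame, one row per SNR level: peaks and thresholds.
#' @export
sweep_snr <- function(model, snr_grid_db, seed = 1, pair = c(1, 2),
                      band = c(50, 60), n_samples = 5e4, fs = 200,
                      seg_len = 256, n_surrogates = 0, percentile = 99.9) {
  x <- simulate_mvar(model, n_samples, seed = seed, fs = fs)
  N <- n_channels(x)
  i <- pair[1]; j <- pair[2]
  rows <- lapply(seq_along(snr_grid_db), function(k) {
    snr <- snr_grid_db[k]
    lam <- vapply(seq_len(N), function(ch)
      lambda_for_snr(x, ch, snr, band = band, seg_len = seg_len), 0)
    y <- observe(x, observation_spec(noise_scale = lam, snr_band = band),
                 seed = child_seed(seed, 100 + k))
    S <- spectral_matrix(y, seg_len = seg_len)
    d <- npd_decompose(S, i, j)
    g <- pairwise_npg(S, i, j)
    out <- data.frame(snr_db = snr,
                      coherence = peak_of(d$coherence),
                      npd = peak_of(d$forward),
                      npg = peak_of(g$granger$forward))
    if (n_surrogates > 0) {
      out$npd_threshold <- permutation_threshold(
        function(s) npd_decompose(spectral_matrix(s, seg_len = seg_len), i, j)$forward[-1],
        y, n = n_surrogates, percentile = percentile,
        seed = child_seed(seed, 200 + k))[1]
      out$npg_threshold <- permutation_threshold(
        function(s) pairwise_npg(spectral_matrix(s, seg_len = seg_len), i, j)$granger$forward[-1],
        y, n = n_surrogates, percentile = percentile,
        seed = child_seed(seed, 300 + k))[1]
    }
    out
  })
  do.call(rbind, rows)
}

#' Sweep the between-channel SNR difference on a symmetric model
#'
#' For a reciprocally coupled 2-node model (ground truth: symmetric dFC),
#' channel `pair[2]` (Y) is held at `fixed_snr_db` while channel `pair[1]`
#' (X) is noised to give each requested `delta = SNR_X - SNR_Y`. Records the
#' peak of each direction and the directionality differences
#' `dNPD = peak(X->Y) - peak(Y->X)` and likewise `dNPG`.
#'
#' @param model a stable 2-node [mvar_model()].
#' @param delta_grid_db vector of SNR differences in dB.
#' @param fixed_snr_db SNR of the fixed channel (default +13 dB).
#' @inheritParams sweep_snr
#' @return data.frame with one row per delta.
#' @export
sweep_delta_snr <- function(model, delta_grid_db, fixed_snr_db = 13, seed = 1,
                            pair = c(1, 2), band = c(50, 60), n_samples = 5e4,
                            fs = 200, seg_len = 256) {
  x <- simulate_mvar(model, n_samples, seed = seed, fs = fs)
  i <- pair[1]; j <- pair[2]
  lam_y <- lambda_for_snr(x, j, fixed_snr_db, band = band, seg_len = seg_len)
  rows <- lapply(seq_along(delta_grid_db), function(k) {
    delta <- delta_grid_db[k]
    lam_x <- lambda_for_snr(x, i, fixed_snr_db + delta, band = band, seg_len = seg_len)
    lam <- numeric(n_channels(x)); lam[i] <- lam_x; lam[j] <- lam_y
    y <- observe(x, observation_spec(noise_scale = lam, snr_band = band),
                 seed = child_seed(seed, 400 + k))
    S <- spectral_matrix(y, seg_len = seg_len)
    d <- npd_decompose(S, i, j)
    g <- pairwise_npg(S, i, j)
    data.frame(delta_snr_db = delta,
               npd_xy = peak_of(d$forward), npd_yx = peak_of(d$reverse),
               npg_xy = peak_of(g$granger$forward), npg_yx = peak_of(g$granger$reverse),
               dnpd = peak_of(d$forward) - peak_of(d$reverse),
               dnpg = peak_of(g$granger$forward) - peak_of(g$granger$reverse))
  })
  do.call(rbind, rows)
}

#' Sweep instantaneous signal mixing
#'
#' No observation noise; for each target shared variance the mixing matrix is
#' calibrated with [calibrate_mixing()] and the peaks of coherence, lagged
#' (forward) NPD, zero-lag NPD and forward NPG for the pair are recorded.
#'
#' @param model a stable [mvar_model()].
#' @param shared_variance_grid values in \[0, 1).
#' @inheritParams sweep_snr
#' @return data.frame with one row per mixing level.
#' @export
sweep_mixing <- function(model, shared_variance_grid, seed = 1, pair = c(1, 2),
                         n_samples = 5e4, fs = 200, seg_len = 256,
                         band = c(50, 60)) {
  x <- simulate_mvar(model, n_samples, seed = seed, fs = fs)
  i <- pair[1]; j <- pair[2]
  rows <- lapply(seq_along(shared_variance_grid), function(k) {
    sv <- shared_variance_grid[k]
    L <- calibrate_mixing(x, sv)
    y <- observe(x, observation_spec(mixing = L, snr_band = band),
                 seed = child_seed(seed, 600 + k))
    S <- spectral_matrix(y, seg_len = seg_len)
    d <- npd_decompose(S, i, j)
    g <- pairwise_npg(S, i, j)
    data.frame(shared_variance = sv,
               coherence = peak_of(d$coherence),
               npd_forward = peak_of(d$forward),
               npd_zero = peak_of(d$zero),
               npg = peak_of(g$granger$forward))
  })
  do.call(rbind, rows)
}

#' Sweep the observation SNR of the third (reference) node
#'
#' Builds one of three triadic architectures with identical node dynamics and
#' identical couplings (lag 2, coefficient `coupling`): serial
#' `X -> Z -> Y`, feedforward `X -> Y -> Z`, or recurrent
#' `X -> Y -> Z -> X`. For each SNR of channel Z (`Inf` = noise free) the
#' X -> Y estimates are recorded: unconditioned NPD, NPD conditioned on Z,
#' pairwise NPG, and multivariate NPG in both the conditional
#' (`mvnpg_cond`) and full-factorization (`mvnpg`) forms (see
#' [multivariate_npg()]). When a noise-free relay makes the spectral matrix
#' near singular the factorization is retried with diagonal loading.
#'
#' @param architecture `"serial"`, `"feedforward"` or `"recurrent"`.
#' @param ref_snr_grid_db SNR grid for channel Z, dB (may include `Inf`).
#' @param coupling edge coefficient (default 0.5).
#' @inheritParams sweep_snr
#' @return data.frame with one row per SNR level.
#' @export
sweep_conditioning_snr <- function(architecture = c("serial", "feedforward", "recurrent"),
                                   ref_snr_grid_db, seed = 1, coupling = 0.5,
                                   band = c(50, 60), n_samples = 5e4, fs = 200,
                                   seg_len = 256, peak_hz = 55) {
  architecture <- match.arg(architecture)
  edges <- switch(architecture,
    serial      = data.frame(from = c(1, 3), to = c(3, 2), lag = 2),
    feedforward = data.frame(from = c(1, 2), to = c(2, 3), lag = 2),
    recurrent   = data.frame(from = c(1, 2, 3), to = c(2, 3, 1), lag = 2))
  model <- build_periodic_model(directed_graph(3, edges), coupling = coupling,
                                peak_hz = peak_hz, fs = fs)
  x <- simulate_mvar(model, n_samples, seed = seed, fs = fs)
  rows <- lapply(seq_along(ref_snr_grid_db), function(k) {
    snr_z <- ref_snr_grid_db[k]
    lam <- numeric(3)
    lam[3] <- lambda_for_snr(x, 3, snr_z, band = band, seg_len = seg_len)
    y <- observe(x, observation_spec(noise_scale = lam, snr_band = band),
                 seed = child_seed(seed, 800 + k))
    S <- spectral_matrix(y, seg_len = seg_len)
    d <- npd_decompose(S, 1, 2)
    dc <- conditioned_npd(S, 1, 2, ref = 3)
    g <- pairwise_npg(S, 1, 2)
    mv_try <- function(meth) tryCatch(
      multivariate_npg(S, method = meth),
      error = function(e) multivariate_npg(S, method = meth, diag_loading = TRUE))
    mg <- mv_try("conditional")
    mgf <- mv_try("full")
    data.frame(ref_snr_db = snr_z, architecture = architecture,
               npd = peak_of(d$forward),
               npd_cond = peak_of(dc$forward),
               npg = peak_of(g$granger$forward),
               mvnpg_cond = peak_of(mg$granger[1, 2, ]),
               mvnpg = peak_of(mgf$granger[1, 2, ]))
  })
  do.call(rbind, rows)
}
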