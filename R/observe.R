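#' Observation model specification
#'
#' Maps latent simulated signals onto recorded channels: instantaneous linear
#' mixing by a unit-diagonal matrix `L`, per-channel z-standardization, then
#' additive white observation noise scaled per channel. This emulates volume
#' conduction and measurement noise in electrophysiological recordings.
#'
#' @param mixing N-by-N mixing matrix with unit diagonal (default identity).
#' @param noise_scale length-N nonnegative noise scale (lambda) per channel;
#'   a scalar is recycled.
#' @param snr_band length-2 frequency interval (Hz) used for narrowband SNR
#'   accounting (default the 55 Hz peak +/- 5 Hz).
#' @return An object of class `"observation_spec"`.
#' @export
observation_spec <- function(mixing = NULL, noise_scale = 0, snr_band = c(50, 60)) {
  if (!is.null(mixing)) {
    mixing <- as.matrix(mixing)
    if (max(abs(diag(mixing) - 1)) > 1e-12)
      stop("mixing matrix must have unit diagonal")
  }
  stopifnot(all(noise_scale >= 0), length(snr_band) == 2L, snr_band[1] < snr_band[2])
  structure(list(mixing = mixing, noise_scale = noise_scale, snr_band = snr_band),
            class = "observation_spec")
}

#' Apply the observation model to a simulated time series
#'
#' Computes `Y = z(L X) + lambda * gamma`: channels are mixed, z-standardized
#' to zero mean and unit variance, and corrupted with i.i.d. zero-mean
#' unit-variance Gaussian noise weighted by each channel's `noise_scale`.
#'
#' @param x a [timeseries()].
#' @param spec an [observation_spec()]; its mixing matrix must be conformable
#'   with `x`.
#' @param seed integer RNG seed for the noise draw.
#' @return A [timeseries()] of observed channels.
#' @export
observe <- function(x, spec, seed) {
  stopifnot(inherits(x, "timeseries"), inherits(spec, "observation_spec"))
  N <- n_channels(x)
  L <- spec$mixing %||% diag(N)
  if (nrow(L) != N) stop("mixing matrix not conformable with the time series")
  if (max(abs(diag(L) - 1)) > 1e-12) stop("mixing matrix must have unit diagonal")
  lambda <- rep_len(spec$noise_scale, N)
  mixed <- L %*% x$data
  zed <- t(scale(t(mixed)))            # z-standardize each channel
  with_seed(seed, {
    noise <- matrix(stats::rnorm(N * ncol(zed)), N) * lambda
    timeseries(zed + noise, fs = x$fs, channel_names = rownames(x$data))
  })
}

#' Narrowband signal-to-noise ratio in decibels
#'
#' `10 log10` of the ratio of mean signal power to mean noise power within a
#' frequency band, computed from two power spectral densities on a common grid.
#'
#' @param signal_psd,noise_psd data.frames with columns `freq` (Hz) and
#'   `power`, e.g. from [psd()].
#' @param band length-2 numeric frequency interval in Hz.
#' @return SNR in dB; `Inf` is returned as an explicit sentinel when the band
#'   noise power is exactly zero.
#' @export
narrowband_snr_db <- function(signal_psd, noise_psd, band) {
  stopifnot(length(band) == 2L, band[1] < band[2])
  if (!isTRUE(all.equal(signal_psd$freq, noise_psd$freq)))
    stop("signal and noise spectra must share a frequency grid")
  sel <- signal_psd$freq >= band[1] & signal_psd$freq <= band[2]
  if (!any(sel)) stop("band contains no frequency bins")
  ps <- mean(signal_psd$power[sel])
  pn <- mean(noise_psd$power[sel])
  if (pn == 0) return(Inf)
  10 * log10(ps / pn)
}

#' Noise scale achieving a target narrowband SNR
#'
#' Inverts the monotone map from the noise scale `lambda` to the narrowband
#' SNR of an observed channel. The channel is z-standardized (as [observe()]
#' does before adding noise), its band power is estimated by Welch-style
#' segment averaging, and `lambda` is solved against the flat one-sided
#' density `2 / fs` of unit-variance white noise.
#'
#' @param x a [timeseries()].
#' @param channel channel index.
#' @param target_snr_db target SNR in dB; `Inf` returns `lambda = 0`.
#' @param band length-2 frequency interval in Hz.
#' @param seg_len segment length for the band-power estimate (default 256).
#' @return Nonnegative scalar `lambda`.
#' @export
lambda_for_snr <- function(x, channel, target_snr_db, band, seg_len = 256) {
  stopifnot(inherits(x, "timeseries"), channel >= 1, channel <= n_channels(x))
  if (is.infinite(target_snr_db) && target_snr_db > 0) return(0)
  stopifnot(is.finite(target_snr_db))
  z <- timeseries(t(scale(x$data[channel, , drop = TRUE]))[1, , drop = FALSE], fs = x$fs)
  S <- spectral_matrix(z, seg_len = seg_len)
  sp <- psd(S, 1)
  sel <- sp$freq >= band[1] & sp$freq <= band[2]
  if (!any(sel)) stop("band contains no frequency bins")
  p_sig <- mean(sp$power[sel])
  if (p_sig <= 0) stop("channel has no power in the requested band; target unreachable")
  p_unit_noise <- 2 / x$fs
  sqrt(p_sig / (p_unit_noise * 10^(target_snr_db / 10)))
}

#' Mixing matrix calibrated to a target shared variance
#'
#' Shared variance is defined operationally as the squared zero-lag Pearson
#' correlation between pairs of observed channels. A symmetric uniform
#' off-diagonal coefficient is solved numerically (bisection on \[0, 1\)) so
#' the mean pairwise squared correlation of the mixed, z-standardized signals
#' hits the target.
#'
#' @param x a [timeseries()] of the unmixed signals.
#' @param shared_variance target in \[0, 1).
#' @return N-by-N unit-diagonal mixing matrix.
#' @export
calibrate_mixing <- function(x, shared_variance) {
  stopifnot(shared_variance >= 0, shared_variance < 1)
  N <- n_channels(x)
  if (N < 2L) stop("need at least two channels to mix")
  sv <- function(l) {
    L <- matrix(l, N, N); diag(L) <- 1
    Y <- L %*% x$data
    cc <- stats::cor(t(Y))
    mean(cc[upper.tri(cc)]^2)
  }
  base <- sv(0)
  if (shared_variance <= base) {
    L <- diag(N)
    return(L)
  }
  l <- stats::uniroot(function(l) sv(l) - shared_variance,
                      lower = 0, upper = 1 - 1e-6, tol = 1e-7)$root
  L <- matrix(l, N, N); diag(L) <- 1
  L
}
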