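# Phase-randomization surrogates and permutation confidence limits.

#' Phase-randomization surrogate of a multichannel time series
#'
#' Each channel's discrete Fourier amplitude spectrum is kept exactly while
#' its phases are replaced by independent uniform draws (conjugate-symmetric;
#' the DC and Nyquist bins keep their original phase so the output is real).
#' Channels are randomized independently, destroying any cross-channel
#' dependence while preserving every autospectrum.
#'
#' @param x a [timeseries()] with T >= 2 samples.
#' @param seed integer RNG seed.
#' @return A [timeseries()] of the same dimensions.
#' @export
phase_randomize <- function(x, seed) {
  stopifnot(inherits(x, "timeseries"), ncol(x$data) >= 2L)
  T <- ncol(x$data); N <- n_channels(x)
  m <- T %/% 2L
  with_seed(seed, {
    out <- x$data
    for (ch in seq_len(N)) {
      X <- stats::fft(x$data[ch, ])
      nfree <- if (T %% 2L == 0L) m - 1L else m
      if (nfree > 0L) {
        ph <- stats::runif(nfree, 0, 2 * pi)
        idx <- 2:(nfree + 1L)
        X[idx] <- Mod(X[idx]) * exp(1i * ph)
        X[T + 2L - idx] <- Conj(X[idx])
      }
      out[ch, ] <- Re(stats::fft(X, inverse = TRUE)) / T
    }
    timeseries(out, fs = x$fs, channel_names = rownames(x$data))
  })
}

#' Permutation confidence limit from phase-randomization surrogates
#'
#' Evaluates a connectivity metric on `n` independent surrogate realizations
#' and returns the requested empirical percentile of the pooled summary. The
#' default pooling takes the maximum of the metric over frequency bins
#' (family-wise control across the spectrum, matching a single horizontal
#' confidence line per spectrum); per-frequency pooling is available via
#' `pool = "none"`, in which case a per-bin threshold vector is returned.
#'
#' The percentile uses the inverse-ECDF convention (order statistic
#' `ceiling(n * p / 100)`), so `n = 1000` at the 99.9th percentile returns the
#' second-largest sample.
#'
#' @param metric function mapping a [timeseries()] to a numeric vector (a
#'   spectrum) or scalar.
#' @param x the original [timeseries()].
#' @param n number of surrogate realizations (>= 100 for a reported
#'   threshold; smaller values error).
#' @param percentile percentile in (50, 100); default 99.9 (P = 0.001).
#' @param seed integer RNG seed; surrogate r gets child seed r.
#' @param pool `"max"` (default) or `"none"`.
#' @return Scalar threshold (`pool = "max"`) or per-bin vector
#'   (`pool = "none"`), with the surrogate samples attached as attribute
#'   `"samples"`.
#' @export
permutation_threshold <- function(metric, x, n = 1000, percentile = 99.9, seed = 1,
                                  pool = c("max", "none")) {
  pool <- match.arg(pool)
  stopifnot(n >= 100, percentile > 50, percentile < 100)
  vals <- vector("list", n)
  failures <- 0L
  for (r in seq_len(n)) {
    sur <- phase_randomize(x, seed = child_seed(seed, r))
    v <- tryCatch(metric(sur), error = function(e) NULL)
    if (is.null(v)) failures <- failures + 1L else vals[[r]] <- v
  }
  if (failures > 0.01 * n)
    stop(sprintf("metric failed on %d of %d surrogates; aborting", failures, n))
  vals <- vals[!vapply(vals, is.null, TRUE)]
  q1 <- function(s) sort(s)[ceiling(length(s) * percentile / 100)]
  if (pool == "max") {
    samples <- vapply(vals, function(v) max(v, na.rm = TRUE), 0)
    thr <- q1(samples)
  } else {
    mat <- do.call(rbind, vals)
    thr <- apply(mat, 2, q1)
    samples <- mat
  }
  attr(thr, "samples") <- samples
  attr(thr, "n_realizations") <- length(vals)
  attr(thr, "percentile") <- percentile
  thr
}
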