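# Segment-averaged Hanning-tapered cross-spectral estimation.

new_spectral_matrix <- function(freqs, S, n_segments, seg_len, fs) {
  structure(list(freqs = freqs, S = S, n_segments = n_segments,
                 seg_len = as.integer(seg_len), fs = fs,
                 n_channels = dim(S)[1]),
            class = "spectral_matrix")
}

#' @export
print.spectral_matrix <- function(x, ...) {
  cat(sprintf("<spectral_matrix> %d channels, %d frequencies (0-%g Hz), %s segments of %d samples\n",
              x$n_channels, length(x$freqs), max(x$freqs),
              format(x$n_segments), x$seg_len))
  invisible(x)
}

#' Estimate the cross-spectral density matrix
#'
#' Splits each channel into disjoint segments of `seg_len` samples, removes
#' each segment's mean, applies a Hanning taper (power-normalized), and
#' averages cross-periodograms over segments. The result is the two-sided
#' cross-spectral density on the one-sided grid `k * fs / seg_len`,
#' `k = 0..seg_len/2`; [psd()] returns the one-sided density whose integral
#' over \[0, Nyquist\] recovers the signal variance.
#'
#' @param x a [timeseries()].
#' @param seg_len segment length in samples; a power of two is recommended
#'   (a warning is issued otherwise). Default 256 (~1.3 s at 200 Hz).
#' @return A `"spectral_matrix"` with fields `freqs`, `S` (N x N x F complex
#'   array), `n_segments`, `seg_len`, `fs`.
#' @export
spectral_matrix <- function(x, seg_len = 256) {
  stopifnot(inherits(x, "timeseries"))
  seg_len <- as.integer(seg_len)
  T <- ncol(x$data); N <- n_channels(x)
  if (T < seg_len) stop("time series shorter than one segment")
  if (bitwAnd(seg_len, seg_len - 1L) != 0L)
    warning("seg_len is not a power of two; frequency grid will be irregular in base-2 terms")
  nseg <- T %/% seg_len
  if (nseg < 2L) stop("fewer than 2 segments available; reduce seg_len")
  w <- 0.5 * (1 - cos(2 * pi * (0:(seg_len - 1)) / (seg_len - 1)))  # Hanning
  U <- sum(w^2)
  m <- seg_len %/% 2L
  keep <- seq_len(m + 1L)
  # Fourier coefficients per channel: columns are segments
  FT <- vector("list", N)
  for (ch in seq_len(N)) {
    segs <- matrix(x$data[ch, seq_len(nseg * seg_len)], nrow = seg_len)
    segs <- sweep(segs, 2, colMeans(segs))   # per-segment demean
    FT[[ch]] <- stats::mvfft(segs * w)[keep, , drop = FALSE]
  }
  S <- array(0 + 0i, dim = c(N, N, m + 1L))
  scale <- 1 / (x$fs * U * nseg)
  for (i in seq_len(N)) {
    for (j in i:N) {
      cs <- rowSums(FT[[i]] * Conj(FT[[j]])) * scale
      S[i, j, ] <- cs
      if (j > i) S[j, i, ] <- Conj(cs) else S[i, i, ] <- Re(cs)
    }
  }
  freqs <- (0:m) * x$fs / seg_len
  new_spectral_matrix(freqs, S, nseg, seg_len, x$fs)
}

#' One-sided power spectral density of one channel
#'
#' @param S a `"spectral_matrix"`.
#' @param i channel index.
#' @return data.frame with columns `freq` (Hz) and `power` (one-sided density;
#'   interior bins carry the doubled two-sided density so that
#'   `sum(power) * fs / seg_len` approximates the channel variance).
#' @export
psd <- function(S, i) {
  stopifnot(inherits(S, "spectral_matrix"))
  p <- Re(S$S[i, i, ])
  mult <- rep(2, length(p))
  mult[1] <- 1
  if (S$seg_len %% 2L == 0L) mult[length(p)] <- 1
  data.frame(freq = S$freqs, power = p * mult)
}

#' Magnitude-squared coherence between two channels
#'
#' `|S_ji|^2 / (S_ii S_jj)` per frequency, bounded in \[0, 1\]. Frequencies
#' where either autospectrum is zero yield `NA` (flagged undefined, not 0).
#'
#' @param S a `"spectral_matrix"`.
#' @param i,j distinct channel indices.
#' @return data.frame with columns `freq` and `coherence`.
#' @export
coherence <- function(S, i, j) {
  stopifnot(inherits(S, "spectral_matrix"), i != j)
  sii <- Re(S$S[i, i, ]); sjj <- Re(S$S[j, j, ])
  coh <- Mod(S$S[j, i, ])^2 / (sii * sjj)
  bad <- sii <= 0 | sjj <= 0
  coh[bad] <- NA_real_
  coh <- pmin(coh, 1)
  data.frame(freq = S$freqs, coherence = coh)
}

# Subset a spectral matrix to a channel subset (order preserved as given).
subset_spectral <- function(S, idx) {
  new_spectral_matrix(S$freqs, S$S[idx, idx, , drop = FALSE],
                      S$n_segments, S$seg_len, S$fs)
}
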