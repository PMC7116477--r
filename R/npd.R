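# Non-parametric directionality: MMSE pre-whitening and decomposition of
# coherence into reverse / zero-lag / forward components by time lag.

#' MMSE pre-whitening of a spectral matrix
#'
#' Normalizes every cross-spectrum by the geometric mean of the corresponding
#' autospectra: `Fw_ij = S_ij / sqrt(S_ii S_jj)`. The whitened matrix has unit
#' diagonal at every frequency and its off-diagonal squared magnitudes equal
#' the coherence, so directionality can be read off the whitened
#' cross-spectrum alone.
#'
#' @param S a `"spectral_matrix"` with strictly positive autospectra.
#' @return An object of class `"whitened_spectral_matrix"` with fields
#'   `freqs` and `Fw` (N x N x F complex array, unit diagonal).
#' @export
prewhiten <- function(S) {
  stopifnot(inherits(S, "spectral_matrix"))
  N <- S$n_channels
  auto <- vapply(seq_len(N), function(i) Re(S$S[i, i, ]), numeric(length(S$freqs)))
  for (i in seq_len(N)) {
    if (any(auto[, i] <= 0)) {
      k <- which(auto[, i] <= 0)[1]
      stop(sprintf("autospectrum of channel %d is zero at %.3f Hz; cannot pre-whiten",
                   i, S$freqs[k]))
    }
  }
  Fw <- S$S
  for (i in seq_len(N)) {
    for (j in seq_len(N)) {
      Fw[i, j, ] <- S$S[i, j, ] / sqrt(auto[, i] * auto[, j])
    }
  }
  structure(list(freqs = S$freqs, Fw = Fw, seg_len = S$seg_len, fs = S$fs,
                 n_channels = N),
            class = "whitened_spectral_matrix")
}

# Two-sided Hermitian extension of a one-sided whitened cross-spectrum.
two_sided <- function(v, seg_len) {
  n <- seg_len
  m <- n %/% 2L
  full <- complex(n)
  full[1:(m + 1L)] <- v
  if (m > 1L) full[(m + 2L):n] <- Conj(v[m:2])
  full
}

#' Whitened lag-correlation function
#'
#' Inverse Fourier transform of the whitened cross-spectrum between channels
#' `i` and `j` (Hermitian-extended to the full circle), giving the real lag
#' correlation `rho(tau)`. Positive lags correspond to activity in `i`
#' preceding activity in `j` (i drives j). By discrete Parseval the sum of
#' `rho^2` over all lags equals the mean coherence over the two-sided
#' frequency grid.
#'
#' @param Fw a `"whitened_spectral_matrix"` from [prewhiten()].
#' @param i,j distinct channel indices (direction i -> j at positive lags).
#' @return data.frame with columns `lag` (samples, from `-(seg_len/2 - 1)` to
#'   `+seg_len/2`) and `rho`.
#' @export
lag_correlation <- function(Fw, i, j) {
  stopifnot(inherits(Fw, "whitened_spectral_matrix"), i != j)
  n <- Fw$seg_len
  m <- n %/% 2L
  fw <- two_sided(Fw$Fw[j, i, ], n)     # f_YX with Y = j (target), X = i (source)
  rho <- Re(stats::fft(fw, inverse = TRUE)) / n
  lag <- c(0:m, -(m - 1L):-1L)
  ord <- order(lag)
  data.frame(lag = lag[ord], rho = rho[ord])
}

#' Decompose coherence into directional components by time lag
#'
#' The whitened cross-spectrum between `i` and `j` is transformed to the lag
#' domain, masked into reverse (`tau < 0`), zero-lag (`tau = 0`) and forward
#' (`tau > 0`) parts, and each masked sequence is Fourier-transformed back.
#' The three magnitude-squared spectra are rescaled at each frequency by the
#' ratio of their relative magnitudes so that they sum exactly to the
#' coherence. The single direction-ambiguous lag bin at `tau = seg_len/2`
#' (where `+tau` and `-tau` coincide on the circular lag grid) is pooled with
#' the symmetric zero-lag component.
#'
#' Scalar components integrate `rho^2` over the same lag ranges; their sum
#' equals the lag-domain sum of `rho^2` and (by Parseval) the mean coherence.
#'
#' @param S a `"spectral_matrix"`.
#' @param i,j distinct channel indices; `forward` is the i -> j component.
#' @return An object of class `"npd_result"` with fields `freqs`, `coherence`,
#'   `forward`, `reverse`, `zero` (component spectra summing to coherence),
#'   `raw` (the unnormalized masked-transform spectra), `scalar` (named vector
#'   `reverse`, `zero`, `forward`), `rho` (lag-correlation data.frame), and
#'   `pair = c(i, j)`.
#' @export
npd_decompose <- function(S, i, j) {
  stopifnot(i != j)
  Fw <- if (inherits(S, "whitened_spectral_matrix")) S else prewhiten(S)
  n <- Fw$seg_len
  m <- n %/% 2L
  fw <- two_sided(Fw$Fw[j, i, ], n)
  rho <- Re(stats::fft(fw, inverse = TRUE)) / n
  # circular lag index: position 1 is tau = 0, 2..m are tau = 1..m-1,
  # m+1 is the ambiguous tau = +/- m bin, m+2..n are tau = -(m-1)..-1
  mask_fwd <- mask_rev <- mask_zero <- rep(0, n)
  mask_zero[1] <- 1
  mask_zero[m + 1L] <- 1                      # ambiguous Nyquist-lag bin
  if (m > 1L) mask_fwd[2:m] <- 1
  if (m > 1L) mask_rev[(m + 2L):n] <- 1
  sp <- function(mask) Mod(stats::fft(rho * mask))^2
  fwd <- sp(mask_fwd); rev <- sp(mask_rev); zer <- sp(mask_zero)
  coh <- Mod(fw)^2
  tot <- fwd + rev + zer
  ratio <- ifelse(tot > 0, coh / tot, 0)      # 0/0 guard at zero coherence
  keep <- 1:(m + 1L)
  res <- structure(list(
    freqs = Fw$freqs,
    coherence = coh[keep],
    forward = (fwd * ratio)[keep],
    reverse = (rev * ratio)[keep],
    zero = (zer * ratio)[keep],
    raw = list(forward = fwd[keep], reverse = rev[keep], zero = zer[keep]),
    scalar = c(reverse = sum((rho * mask_rev)^2),
               zero = sum((rho * mask_zero)^2),
               forward = sum((rho * mask_fwd)^2)),
    rho = {
      lag <- c(0:m, -(m - 1L):-1L); ord <- order(lag)
      data.frame(lag = lag[ord], rho = rho[ord])
    },
    pair = c(i, j),
    fs = Fw$fs, seg_len = n), class = "npd_result")
  res
}

#' @export
print.npd_result <- function(x, ...) {
  cat(sprintf("<npd_result> pair %d -> %d, %d frequencies\n",
              x$pair[1], x$pair[2], length(x$freqs)))
  cat(sprintf("  scalar components: reverse %.4f | zero %.4f | forward %.4f\n",
              x$scalar["reverse"], x$scalar["zero"], x$scalar["forward"]))
  pk <- which.max(x$forward[-1]) + 1L
  cat(sprintf("  peak forward %.4f at %.1f Hz\n", x$forward[pk], x$freqs[pk]))
  invisible(x)
}

# Peak of a component spectrum excluding the DC bin.
peak_excl_dc <- function(freqs, spec) {
  max(spec[-1], na.rm = TRUE)
}
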