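# Conditioned (partialized) NPD: remove the linear contribution of a
# reference channel from the spectral matrix, then decompose the partial
# coherence into the same three directional components.

#' Partialize a spectral matrix on a reference channel
#'
#' Removes the linear (frequency-domain regression) contribution of channel
#' `ref` from every remaining auto- and cross-spectrum:
#' `f_ab|z = f_ab - f_az f_zb / f_zz`. This is the standard single-predictor
#' partial-spectra construction; partial coherence computed from the result
#' is the coherence between `a` and `b` with `z` as predictor.
#'
#' @param S a `"spectral_matrix"` with at least 3 channels.
#' @param ref reference channel index; its autospectrum must be strictly
#'   positive at every retained frequency.
#' @return A `"conditioned_spectral_matrix"` (also usable as a
#'   `"spectral_matrix"`) over the remaining channels, with attributes
#'   `ref_channel` (original index) and `channel_map` (original indices of the
#'   retained channels, in order).
#' @export
partialize <- function(S, ref) {
  stopifnot(inherits(S, "spectral_matrix"), S$n_channels >= 3L,
            ref >= 1, ref <= S$n_channels)
  szz <- Re(S$S[ref, ref, ])
  if (any(szz <= 0)) stop("reference channel has zero autospectrum; cannot partialize")
  keep <- setdiff(seq_len(S$n_channels), ref)
  Np <- length(keep)
  Sp <- array(0 + 0i, dim = c(Np, Np, length(S$freqs)))
  for (a in seq_len(Np)) {
    for (b in seq_len(Np)) {
      ia <- keep[a]; ib <- keep[b]
      Sp[a, b, ] <- S$S[ia, ib, ] - S$S[ia, ref, ] * S$S[ref, ib, ] / szz
    }
  }
  for (a in seq_len(Np)) Sp[a, a, ] <- Re(Sp[a, a, ])  # numerically real
  out <- new_spectral_matrix(S$freqs, Sp, S$n_segments, S$seg_len, S$fs)
  class(out) <- c("conditioned_spectral_matrix", class(out))
  out$ref_channel <- ref
  out$channel_map <- keep
  out
}

#' NPD conditioned on a reference channel
#'
#' Applies the full NPD pipeline (pre-whitening, lag correlation, directional
#' decomposition) to the partialized spectral matrix, so the three components
#' sum to the partial coherence given `ref`. With serial routing
#' `i -> ref -> j` and a fully observed reference, the conditioned estimate
#' vanishes; as the reference observation degrades, it rises back towards the
#' unconditioned NPD.
#'
#' @param S a `"spectral_matrix"` (N >= 3).
#' @param i,j channel indices of the pair (original indexing of `S`).
#' @param ref reference channel index, distinct from `i` and `j`.
#' @return An `"npd_result"`; the `pair` field keeps the original indices and
#'   the result carries a `ref_channel` field.
#' @export
conditioned_npd <- function(S, i, j, ref) {
  stopifnot(length(unique(c(i, j, ref))) == 3L)
  Sp <- partialize(S, ref)
  ip <- match(i, Sp$channel_map)
  jp <- match(j, Sp$channel_map)
  res <- npd_decompose(Sp, ip, jp)
  res$pair <- c(i, j)
  res$ref_channel <- ref
  res
}
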