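# Internal helpers shared across modules.

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(as.integer(seed))
  force(code)
}

# Derive a child seed from a parent seed and an index, staying inside the
# 32-bit integer range so set.seed() never overflows.
child_seed <- function(seed, k) {
  as.integer((as.numeric(seed) * 48271 + 104729 * as.numeric(k)) %% 2147483647)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# ---- frequency-stacked matrix algebra -------------------------------------
# Arrays with dim c(N, N, F): one small matrix per frequency, vectorised over
# the frequency dimension so the Wilson iteration stays fast in pure R.

arr_mult <- function(A, B) {
  dA <- dim(A); dB <- dim(B)
  stopifnot(dA[2] == dB[1], dA[3] == dB[3])
  out <- array(0 + 0i, dim = c(dA[1], dB[2], dA[3]))
  for (i in seq_len(dA[1])) {
    for (j in seq_len(dB[2])) {
      acc <- A[i, 1, ] * B[1, j, ]
      if (dA[2] > 1L) for (k in 2:dA[2]) acc <- acc + A[i, k, ] * B[k, j, ]
      out[i, j, ] <- acc
    }
  }
  out
}

# Conjugate transpose per frequency.
arr_ctrans <- function(A) {
  out <- Conj(aperm(A, c(2, 1, 3)))
  out
}

# Per-frequency inverse; closed forms for N <= 2, LU solve otherwise.
arr_inv <- function(A) {
  d <- dim(A); N <- d[1]; F <- d[3]
  if (N == 1L) {
    out <- array(1 / A[1, 1, ], dim = d)
    return(out)
  }
  if (N == 2L) {
    det <- A[1, 1, ] * A[2, 2, ] - A[1, 2, ] * A[2, 1, ]
    out <- array(0 + 0i, dim = d)
    out[1, 1, ] <- A[2, 2, ] / det
    out[2, 2, ] <- A[1, 1, ] / det
    out[1, 2, ] <- -A[1, 2, ] / det
    out[2, 1, ] <- -A[2, 1, ] / det
    return(out)
  }
  if (N == 3L) {
    # adjugate / determinant, vectorised over frequency
    a <- A[1, 1, ]; b <- A[1, 2, ]; c <- A[1, 3, ]
    d2 <- A[2, 1, ]; e <- A[2, 2, ]; f <- A[2, 3, ]
    g <- A[3, 1, ]; h <- A[3, 2, ]; i <- A[3, 3, ]
    co11 <- e * i - f * h; co12 <- -(d2 * i - f * g); co13 <- d2 * h - e * g
    co21 <- -(b * i - c * h); co22 <- a * i - c * g; co23 <- -(a * h - b * g)
    co31 <- b * f - c * e; co32 <- -(a * f - c * d2); co33 <- a * e - b * d2
    det <- a * co11 + b * co12 + c * co13
    out <- array(0 + 0i, dim = dim(A))
    out[1, 1, ] <- co11 / det; out[1, 2, ] <- co21 / det; out[1, 3, ] <- co31 / det
    out[2, 1, ] <- co12 / det; out[2, 2, ] <- co22 / det; out[2, 3, ] <- co32 / det
    out[3, 1, ] <- co13 / det; out[3, 2, ] <- co23 / det; out[3, 3, ] <- co33 / det
    return(out)
  }
  out <- array(0 + 0i, dim = d)
  for (k in seq_len(F)) out[, , k] <- solve(A[, , k])
  out
}

# FFT along the third (frequency) dimension of an [N, N, F] array.
arr_fft <- function(A, inverse = FALSE) {
  d <- dim(A)
  out <- array(0 + 0i, dim = d)
  for (i in seq_len(d[1])) {
    for (j in seq_len(d[2])) {
      v <- stats::fft(A[i, j, ], inverse = inverse)
      if (inverse) v <- v / d[3]
      out[i, j, ] <- v
    }
  }
  out
}
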