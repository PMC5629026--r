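# Internal numerical helpers.

# Deterministic sub-seed derivation so one master seed controls every
# source of randomness in a run. Kept well below 2^31.
derive_seed <- function(seed, index) {
  s <- (as.double(seed) %% 2147483647) * 7919 + as.double(index) * 104729
  as.integer(s %% 2147483647)
}

with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

# FFT linear convolution of a signal with a bank of FIR kernels whose FFTs
# are precomputed at size nfft (>= length(x) + kernel length - 1 is the
# caller's responsibility). Returns the "same"-length causal part.
fft_fwd <- function(x, nfft) stats::fft(c(x, numeric(nfft - length(x))))

fft_conv_same <- function(X, Hf, n, nfft) {
  Re(stats::fft(X * Hf, inverse = TRUE))[seq_len(n)] / nfft
}

# Windowed-sinc fractional-delay interpolation: returns x evaluated at
# positions idx - frac (idx integer vector, 0 <= frac < 1), where x is
# treated as samples of a band-limited signal. Half-width M taps per side,
# Blackman window. Caller guarantees idx +/- M stays inside x.
sinc_shift <- function(x, idx, frac, M = 32L) {
  if (frac == 0) return(x[idx])
  m <- seq.int(-M, M)
  t <- m + frac
  h <- sin(pi * t) / (pi * t)            # t never 0 when 0 < frac < 1
  w <- 0.42 + 0.5 * cos(pi * m / M) + 0.08 * cos(2 * pi * m / M)
  h <- h * w
  y <- numeric(length(idx))
  for (j in seq_along(m)) y <- y + h[j] * x[idx + m[j]]
  y
}
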