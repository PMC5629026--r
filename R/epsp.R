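#' EPSP transform of band signals
#'
#' Converts each band-limited signal into a train of stereotyped
#' postsynaptic-potential-like pulses that preserve only phase-locking
#' information: the signal is reduced to unit impulses at its positive-going
#' zero crossings (sample `k` with `x[k-1] < 0 <= x[k]`; the crossing is
#' assigned to the later sample), and the impulse train is convolved with a
#' Gaussian window of full width at half maximum `epsp_width_ms`
#' (peak amplitude 1, truncated at +/- 3 sigma, centred on the crossing).
#'
#' The output is non-negative, has the same length as the input, and is
#' invariant to positive amplitude scaling of the input - the property that
#' makes the downstream beam profiles narrow and frequency-stable.
#'
#' `epsp_width_ms` is the *total duration* of the pulse (the window's
#' support, truncated at `+/- 3 sigma`, so `sigma = width / 6`). The 1 ms
#' default emulates the millisecond-scale EPSPs of mammalian brainstem
#' coincidence detectors; a Gaussian whose *half-maximum* width were a
#' full millisecond would smear away all phase-locking above roughly
#' 1 kHz and with it the high-frequency spatial structure the analyzer
#' relies on.
#'
#' @param bands a `band_signals` object with `stage = "filtered"`.
#' @param epsp_width_ms total width (support) of the Gaussian pulse in
#'   milliseconds.
#' @return a `band_signals` object with `stage = "epsp"`.
#' @export
epsp_transform <- function(bands, epsp_width_ms = 1) {
  stopifnot(inherits(bands, "band_signals"))
  if (!identical(bands$stage, "filtered"))
    stop("epsp_transform expects stage = 'filtered' input")
  fs <- bands$sample_rate_hz
  sigma <- epsp_width_ms / 1000 * fs / 6
  M <- as.integer(ceiling(3 * sigma))
  g <- exp(-(seq.int(-M, M))^2 / (2 * sigma^2))
  dims <- dim(bands$values)
  n <- dims[3]
  out <- array(0, dim = dims)
  for (j in seq_len(dims[1])) {
    for (ch in 1:2) {
      x <- bands$values[j, ch, ]
      p <- which(x[-1] >= 0 & x[-n] < 0) + 1L      # positive-going crossings
      if (length(p)) {
        y <- numeric(n + 2L * M)
        for (m in seq.int(-M, M))                  # scatter-add the kernel
          y[p + m + M] <- y[p + m + M] + g[m + M + 1L]
        out[j, ch, ] <- y[(M + 1L):(M + n)]
      }
    }
  }
  structure(
    list(values = out, band_centres_hz = bands$band_centres_hz,
         sample_rate_hz = fs, stage = "epsp"),
    class = "band_signals")
}
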