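# Binaural rendering: sources are continuous-time signals; each channel
# samples the source at t -/+ tau/2, where tau is the interaural delay for
# the current head orientation. Tones are evaluated in closed form at the
# shifted times (exact fractional delay); stochastic/wav sources keep one
# master sample sequence per run and are shifted by windowed-sinc
# interpolation. Whole-sample rounding is deliberately never used here:
# the analyzer quantizes delays, the simulated world does not.

.PAD <- 128L      # sinc half-width + max interaural lag + margin
.PRE <- 8320L     # lead-in samples available before sample 0 (>= context)

# master sample sequence for a stochastic or wav source, cached per scene
source_master <- function(scene, geometry, i) {
  fs <- geometry$sample_rate_hz
  key <- sprintf("src%d_fs%g", i, fs)
  cache <- scene$cache
  if (!is.null(cache[[key]])) return(cache[[key]])
  src <- scene$sources[[i]]
  n <- .PRE + scene$duration_frames * scene$frame_length + .PAD
  x <- switch(src$kind,
    broadband_noise = {
      x <- with_seed(derive_seed(scene$seed, 101 + i), stats::rnorm(n))
      if (!is.null(src$params$band_hz)) {
        X <- stats::fft(x)
        f <- (seq_len(n) - 1) / n * fs
        f <- pmin(f, fs - f)                      # two-sided frequency axis
        X[f < src$params$band_hz[1] | f > src$params$band_hz[2]] <- 0
        x <- Re(stats::fft(X, inverse = TRUE)) / n
      }
      x
    },
    wav_file = {
      w <- read_wav_mono(src$params$path, resample_to = fs)
      if (length(w) < n) w <- rep_len(w, n) else w <- w[seq_len(n)]
      w
    },
    stop("source kind '", src$kind, "' has no master waveform"))
  x <- x / sqrt(mean(x^2))                        # unit broadband RMS
  cache[[key]] <- x
  x
}

# deterministic per-component phases for tonal sources
tone_phases <- function(scene, i, nfreq) {
  with_seed(derive_seed(scene$seed, 501 + i),
            stats::runif(nfreq, 0, 2 * pi))
}

# one channel of source i over samples k0 .. k0+n-1 (k relative to run
# start), delayed by delay_s seconds
source_channel <- function(scene, geometry, i, k0, n, delay_s) {
  fs <- geometry$sample_rate_hz
  src <- scene$sources[[i]]
  if (src$kind %in% c("tone", "tone_complex")) {
    freqs <- src$params$freqs_hz
    if (any(freqs >= fs / 2))
      stop("invalid source: tone frequency at or above Nyquist (",
           fs / 2, " Hz)")
    ph <- tone_phases(scene, i, length(freqs))
    t <- (k0 + seq_len(n) - 1) / fs - delay_s
    amp <- src$level * sqrt(2 / length(freqs))    # unit broadband RMS at level 1
    y <- numeric(n)
    for (j in seq_along(freqs))
      y <- y + amp * sin(2 * pi * freqs[j] * t + ph[j])
    y
  } else {
    x <- source_master(scene, geometry, i)
    D <- fs * delay_s
    di <- floor(D)
    fr <- D - di
    idx <- .PRE + 1L + k0 + seq_len(n) - 1L - as.integer(di)
    if (min(idx) - 32L < 1L || max(idx) + 32L > length(x))
      stop("render window outside the scene's prepared duration")
    src$level * sinc_shift(x, idx, fr)
  }
}

background_block <- function(scene, geometry, channel, k0, n) {
  if (scene$background_noise_level <= 0) return(numeric(n))
  key <- sprintf("bg%d_fs%g", channel, geometry$sample_rate_hz)
  cache <- scene$cache
  if (is.null(cache[[key]])) {
    ntot <- .PRE + scene$duration_frames * scene$frame_length + .PAD
    cache[[key]] <- with_seed(derive_seed(scene$seed, 900000 + channel),
                              stats::rnorm(ntot))
  }
  idx <- .PRE + 1L + k0 + seq_len(n) - 1L
  scene$background_noise_level * cache[[key]][idx]
}

# 2 x n sample block starting at run sample k0 (k0 may be negative down to
# -.PRE, used for filter lead-in context)
render_block <- function(scene, geometry, head_orientation_deg, k0, n) {
  out <- matrix(0, nrow = 2, ncol = n)
  for (i in seq_along(scene$sources)) {
    tau <- itd_for_source(geometry, scene$sources[[i]]$azimuth_deg,
                          head_orientation_deg)
    # positive tau: right mic leads -> right channel advanced by tau/2
    out[1, ] <- out[1, ] + source_channel(scene, geometry, i, k0, n,  tau / 2)
    out[2, ] <- out[2, ] + source_channel(scene, geometry, i, k0, n, -tau / 2)
  }
  out[1, ] <- out[1, ] + background_block(scene, geometry, 1L, k0, n)
  out[2, ] <- out[2, ] + background_block(scene, geometry, 2L, k0, n)
  if (!all(is.finite(out))) stop("non-finite samples rendered")
  out
}

#' Render one binaural frame of a scene
#'
#' Produces the two-channel sample block a rotating microphone pair would
#' capture for `scene` at the given head orientation. Each source is
#' delayed per channel by half its interaural time difference (fractional
#' delays, sinc-interpolated for stochastic sources, exact for tones),
#' scaled to its level, summed, and independent Gaussian background noise
#' is added per channel. Rendering is deterministic given the scene seed.
#'
#' Row 1 of `samples` is the left channel, row 2 the right channel.
#'
#' @param scene a [scene_spec()].
#' @param geometry an [array_geometry()].
#' @param head_orientation_deg allocentric head orientation, degrees.
#' @param frame_index 0-based frame number, `< scene$duration_frames`.
#' @return an object of class `stereo_frame`: list with `samples`
#'   (2 x frame_length matrix), `frame_length`, `head_orientation_deg`.
#' @export
render_frame <- function(scene, geometry, head_orientation_deg = 0,
                         frame_index = 0) {
  stopifnot(inherits(scene, "scene_spec"), inherits(geometry, "array_geometry"))
  if (frame_index < 0 || frame_index >= scene$duration_frames)
    stop("frame_index out of range [0, ", scene$duration_frames - 1, "]")
  N <- scene$frame_length
  samples <- render_block(scene, geometry, head_orientation_deg,
                          k0 = as.integer(frame_index) * N, n = N)
  structure(
    list(samples = samples, frame_length = N,
         head_orientation_deg = head_orientation_deg),
    class = "stereo_frame")
}

#' @export
print.stereo_frame <- function(x, ...) {
  cat(sprintf("<stereo_frame> 2 x %d samples, head at %g deg, RMS %.4g\n",
              x$frame_length, x$head_orientation_deg,
              sqrt(mean(x$samples^2))))
  invisible(x)
}
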