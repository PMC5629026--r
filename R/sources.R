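#' Sound sources for the binaural scene simulator
#'
#' A source is a stationary emitter at a fixed allocentric azimuth. All
#' source waveforms are normalised to unit broadband RMS before the `level`
#' scaling is applied, so co-presented sources with equal `level` are
#' RMS-equalised, matching how competing stimuli are presented in
#' psychoacoustic rigs.
#'
#' @param freq_hz tone frequency in Hz (must stay below Nyquist at render
#'   time).
#' @param freqs_hz numeric vector of component frequencies for a tone
#'   complex.
#' @param azimuth_deg allocentric azimuth of the source in degrees,
#'   `[0, 360)`.
#' @param level linear RMS amplitude of the source.
#' @param band_hz optional length-2 vector `c(lo, hi)`; if given, the noise
#'   is brick-wall band-limited to that range (Hz).
#' @param path path to a mono WAV file (PCM 16/24/32-bit or IEEE float).
#' @return an object of class `earmap_source`.
#' @name sources
NULL

new_source <- function(kind, azimuth_deg, level, params) {
  stopifnot(is.numeric(azimuth_deg), length(azimuth_deg) == 1,
            is.numeric(level), level >= 0)
  structure(
    list(kind = kind, azimuth_deg = azimuth_deg %% 360,
         level = level, params = params),
    class = "earmap_source")
}

#' @rdname sources
#' @export
tone_source <- function(freq_hz, azimuth_deg, level = 1) {
  stopifnot(is.numeric(freq_hz), length(freq_hz) == 1, freq_hz > 0)
  new_source("tone", azimuth_deg, level, list(freqs_hz = freq_hz))
}

#' @rdname sources
#' @export
tone_complex_source <- function(freqs_hz, azimuth_deg, level = 1) {
  stopifnot(is.numeric(freqs_hz), length(freqs_hz) >= 1, all(freqs_hz > 0))
  new_source("tone_complex", azimuth_deg, level, list(freqs_hz = freqs_hz))
}

#' @rdname sources
#' @export
noise_source <- function(azimuth_deg, level = 1, band_hz = NULL) {
  if (!is.null(band_hz))
    stopifnot(length(band_hz) == 2, band_hz[1] >= 0, band_hz[2] > band_hz[1])
  new_source("broadband_noise", azimuth_deg, level, list(band_hz = band_hz))
}

#' @rdname sources
#' @export
wav_source <- function(path, azimuth_deg, level = 1) {
  stopifnot(is.character(path), length(path) == 1)
  new_source("wav_file", azimuth_deg, level, list(path = path))
}

#' @export
print.earmap_source <- function(x, ...) {
  extra <- switch(x$kind,
    tone = sprintf("%g Hz", x$params$freqs_hz),
    tone_complex = sprintf("%d components %g..%g Hz",
                           length(x$params$freqs_hz),
                           min(x$params$freqs_hz), max(x$params$freqs_hz)),
    broadband_noise = if (is.null(x$params$band_hz)) "white"
                      else sprintf("%g-%g Hz", x$params$band_hz[1],
                                   x$params$band_hz[2]),
    wav_file = x$params$path)
  cat(sprintf("<source:%s> az %g deg, level %g (%s)\n",
              x$kind, x$azimuth_deg, x$level, extra))
  invisible(x)
}

#' Acoustic scene specification
#'
#' Bundles the sources, the background noise level, the run duration and
#' the master random seed. The background is white Gaussian noise,
#' independent between the two channels (a diffuse room floor carries no
#' usable interaural structure), with linear RMS `background_noise_level`
#' relative to a unit-RMS source.
#'
#' All stochastic waveforms (source noise, background noise) are generated
#' once per run from sub-seeds derived deterministically from `seed`, so a
#' scene renders bit-identically for a given seed regardless of the order
#' frames are requested in.
#'
#' @param sources list of [sources] (may be empty).
#' @param background_noise_level linear RMS of the per-channel background.
#' @param duration_frames number of frames the scene must be able to render.
#' @param seed integer master seed.
#' @param frame_length samples per stereo frame.
#' @return an object of class `scene_spec`.
#' @export
scene_spec <- function(sources, background_noise_level = 0.1,
                       duration_frames = 120, seed = 1,
                       frame_length = 4096) {
  if (inherits(sources, "earmap_source")) sources <- list(sources)
  stopifnot(is.list(sources),
            all(vapply(sources, inherits, TRUE, "earmap_source")),
            background_noise_level >= 0,
            duration_frames >= 1, frame_length >= 16)
  structure(
    list(sources = sources,
         background_noise_level = background_noise_level,
         duration_frames = as.integer(duration_frames),
         seed = as.integer(seed),
         frame_length = as.integer(frame_length),
         cache = new.env(parent = emptyenv())),
    class = "scene_spec")
}

#' @export
print.scene_spec <- function(x, ...) {
  cat(sprintf("<scene_spec> %d source(s), bg RMS %g, %d frames x %d samples, seed %d\n",
              length(x$sources), x$background_noise_level,
              x$duration_frames, x$frame_length, x$seed))
  for (s in x$sources) print(s)
  invisible(x)
}
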