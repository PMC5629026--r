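#' Microphone array geometry
#'
#' Describes the binaural capture rig: two omnidirectional microphones on a
#' rigid bar that rotates in the horizontal plane. The geometry fixes the
#' maximum interaural lag expressible in whole samples,
#' `K = floor(d * fs / c)`, which in turn fixes the number of delay-and-sum
#' beams (`2K + 1`) the analyzer can steer.
#'
#' Angle conventions used throughout the package: azimuths are measured in
#' degrees in a fixed world (allocentric) frame; `0` deg is the head's
#' frontal midline when the head orientation is `0` deg, and angles increase
#' towards the right of the head. A positive interaural delay means the
#' sound reaches the *right* microphone first.
#'
#' @param mic_spacing_m distance between the microphones in metres.
#' @param speed_of_sound_mps speed of sound in metres per second.
#' @param sample_rate_hz capture sampling rate in Hz.
#' @return an object of class `array_geometry`.
#' @examples
#' geom <- array_geometry()
#' geom$max_lag_samples  # 20 for the default rig
#' @export
array_geometry <- function(mic_spacing_m = 0.145,
                           speed_of_sound_mps = 343,
                           sample_rate_hz = 48000) {
  if (!(is.numeric(mic_spacing_m) && mic_spacing_m > 0))
    stop("mic_spacing_m must be a positive number")
  if (!(is.numeric(speed_of_sound_mps) && speed_of_sound_mps > 0))
    stop("speed_of_sound_mps must be a positive number")
  if (!(is.numeric(sample_rate_hz) && sample_rate_hz > 0))
    stop("sample_rate_hz must be a positive number")
  K <- floor(mic_spacing_m * sample_rate_hz / speed_of_sound_mps)
  if (K < 1)
    stop("invalid geometry: microphone spacing too small for the sampling ",
         "rate (no whole-sample interaural lag exists)")
  structure(
    list(mic_spacing_m = mic_spacing_m,
         speed_of_sound_mps = speed_of_sound_mps,
         sample_rate_hz = sample_rate_hz,
         max_lag_samples = K),
    class = "array_geometry")
}

#' @export
print.array_geometry <- function(x, ...) {
  cat(sprintf("<array_geometry> d = %g m, c = %g m/s, fs = %g Hz (K = %d, %d beams)\n",
              x$mic_spacing_m, x$speed_of_sound_mps, x$sample_rate_hz,
              x$max_lag_samples, 2L * x$max_lag_samples + 1L))
  invisible(x)
}

deg2rad <- function(x) x * pi / 180
rad2deg <- function(x) x * 180 / pi

#' Circular angular distance in degrees
#'
#' Shortest arc between two azimuths on the circle, in `[0, 180]`.
#'
#' @param a,b azimuths in degrees (vectors recycle).
#' @return non-negative degrees.
#' @export
circ_dist_deg <- function(a, b) {
  d <- (a - b) %% 360
  pmin(d, 360 - d)
}

#' Interaural time difference for a source
#'
#' The signed delay between the two microphones for a plane-wave source,
#' `tau = (d / c) * sin(epsilon)`, where `epsilon` is the source azimuth
#' expressed in the head-centred (egocentric) frame,
#' `epsilon = azimuth - head orientation`. Because `sin(180 - e) = sin(e)`,
#' mirror-image positions across the interaural axis produce identical
#' delays: this *is* the front/back ambiguity the mapping stage resolves.
#'
#' Positive delay means the sound arrives at the right microphone first
#' (source to the right of the current midline).
#'
#' @param geometry an [array_geometry()].
#' @param source_azimuth_deg allocentric source azimuth, degrees.
#' @param head_orientation_deg allocentric head orientation, degrees.
#' @return delay in seconds (vectorised over azimuths).
#' @examples
#' itd_for_source(array_geometry(), 90, 0)  # d/c ~ 4.23e-4 s
#' @export
itd_for_source <- function(geometry, source_azimuth_deg,
                           head_orientation_deg = 0) {
  stopifnot(inherits(geometry, "array_geometry"))
  ego <- source_azimuth_deg - head_orientation_deg
  (geometry$mic_spacing_m / geometry$speed_of_sound_mps) * sin(deg2rad(ego))
}

#' Construct the delay-and-sum beam set
#'
#' Beams are steered at every whole-sample interaural lag
#' `k = -K, ..., K` (characteristic delays `T_b = k / fs`), and each lag maps
#' to an arrival angle `theta = asin(c * T_b / d)`. The asin argument is
#' clamped to `[-1, 1]` to absorb floating-point excess, so all angles are
#' real. The centre beam (`T_b = 0`) points at `0` deg and angles increase
#' strictly from `-90` to `+90` deg.
#'
#' @param geometry an [array_geometry()].
#' @return an object of class `beam_set` with fields `lags_samples`,
#'   `delays_s`, `angles_deg` and `n_beams`.
#' @examples
#' make_beam_set(array_geometry())$n_beams  # 41
#' @export
make_beam_set <- function(geometry) {
  stopifnot(inherits(geometry, "array_geometry"))
  K <- geometry$max_lag_samples
  k <- seq.int(-K, K)
  delays <- k / geometry$sample_rate_hz
  arg <- geometry$speed_of_sound_mps * delays / geometry$mic_spacing_m
  arg <- pmin(1, pmax(-1, arg))
  structure(
    list(lags_samples = k,
         delays_s = delays,
         angles_deg = rad2deg(asin(arg)),
         n_beams = length(k)),
    class = "beam_set")
}

#' @export
print.beam_set <- function(x, ...) {
  cat(sprintf("<beam_set> %d beams, lags %d..%d samples, angles %.1f..%.1f deg\n",
              x$n_beams, min(x$lags_samples), max(x$lags_samples),
              min(x$angles_deg), max(x$angles_deg)))
  invisible(x)
}

#' Analytic beam response to a pure tone
#'
#' Closed-form relative response of a delay-and-sum beam steered at
#' `theta` to a unit plane-wave tone of frequency `f` arriving from `psi`:
#'
#' \deqn{A(\psi, \theta) = \sqrt{2 + 2\cos(2\pi f d(\sin\psi - \sin\theta)/c)} / 2}
#'
#' `A` is 1 when the beam points at the source and 0 at full cancellation.
#' At high frequencies (interaural distance beyond half a wavelength)
#' secondary unit-amplitude lobes appear at aliased steering angles; this
#' function is the validation oracle for the audio-domain beamformer chain.
#'
#' @param f tone frequency, Hz.
#' @param arrival_deg arrival angle `psi`, degrees from the frontal midline.
#' @param steering_deg steering angle `theta`, degrees (vectorised).
#' @param geometry an [array_geometry()].
#' @return response amplitude(s) in `[0, 1]`.
#' @export
analytic_response <- function(f, arrival_deg, steering_deg, geometry) {
  stopifnot(inherits(geometry, "array_geometry"))
  d <- geometry$mic_spacing_m
  cc <- geometry$speed_of_sound_mps
  phase <- 2 * pi * f * d *
    (sin(deg2rad(arrival_deg)) - sin(deg2rad(steering_deg))) / cc
  sqrt(pmax(0, 2 + 2 * cos(phase))) / 2
}
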