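# Shared fixtures and oracles, built in code.

default_geom <- array_geometry()        # 0.145 m, 343 m/s, 48 kHz
default_fb <- filterbank_spec()         # 50 linear bands 100-5000 Hz

# lazy cache for expensive shared runs (computed once per test session)
.run_cache <- new.env(parent = emptyenv())
cached <- function(name, expr) {
  if (is.null(.run_cache[[name]])) .run_cache[[name]] <- force(expr)
  .run_cache[[name]]
}

# independent brute-force cross-correlation lag estimate between the two
# channels of a stereo frame (the oracle for rendered interaural delays)
brute_xcorr_lag <- function(frame, max_lag = 20) {
  L <- frame$samples[1, ]
  R <- frame$samples[2, ]
  n <- length(L)
  lags <- -max_lag:max_lag
  cc <- vapply(lags, function(s) {
    if (s >= 0) sum(L[(s + 1):n] * R[seq_len(n - s)])
    else sum(L[seq_len(n + s)] * R[(1 - s):n])
  }, numeric(1))
  lags[which.max(cc)]
}

# band signals holding given per-channel vectors in a single band
make_band_signals <- function(L, R, fc = 1000, fs = 48000,
                              stage = "epsp") {
  vals <- array(0, dim = c(1, 2, length(L)))
  vals[1, 1, ] <- L
  vals[1, 2, ] <- R
  structure(list(values = vals, band_centres_hz = fc,
                 sample_rate_hz = fs, stage = stage),
            class = "band_signals")
}

# ego_map with given energy rows placed on the default beam set
make_ego_map <- function(energy, head = 0, geom = default_geom) {
  beams <- make_beam_set(geom)
  earmap:::new_ego_map(energy, beams,
                       band_centres_hz = seq_len(nrow(energy)),
                       head_orientation_deg = head, frame_length = 4096)
}

# uniform-band evidence with a single spiked angle pair (already mirrored)
spike_evidence <- function(angles, n_bands = 1, value = 1) {
  pdf <- matrix(1e-6, n_bands, 360)
  pdf[, angles + 1] <- value
  normalize_bands(structure(
    list(pdf = pdf, band_centres_hz = seq_len(n_bands),
         head_orientation_deg = 0, angles_deg = 0:359, normalized = FALSE),
    class = "ego_evidence"))
}

# single-band beam-energy profile of a quiet single-tone scene at a given
# head orientation, through the full front end
tone_beam_profile <- function(freq, az, n_frames = 6, head = 0,
                              geom = default_geom, fb = default_fb,
                              stage = "epsp") {
  sc <- scene_spec(list(tone_source(freq, az)), background_noise_level = 0,
                   duration_frames = n_frames, seed = 1)
  N <- sc$frame_length
  block <- earmap:::render_block(sc, geom, head, -N, (n_frames + 1) * N)
  bs <- gammatone_filter(block, fb, geom$sample_rate_hz)
  if (stage == "epsp") bs <- epsp_transform(bs)
  bs$values <- bs$values[, , (N + 1):((n_frames + 1) * N), drop = FALSE]
  S <- earmap:::block_energy_matrix(bs, make_beam_set(geom), N)
  S[which.min(abs(fb$band_centres_hz - freq)), ]
}

# contiguous half-prominence width (degrees) of a beam profile around its
# global maximum
halfprom_width_deg <- function(p, angles) {
  lvl <- min(p) + (max(p) - min(p)) / 2
  i <- which.max(p)
  lo <- i; hi <- i
  while (lo > 1 && p[lo - 1] >= lvl) lo <- lo - 1
  while (hi < length(p) && p[hi + 1] >= lvl) hi <- hi + 1
  angles[hi] - angles[lo]
}

# count circular local maxima above half of the row maximum
count_halfmax_peaks <- function(v) {
  n <- length(v)
  prev <- v[c(n, seq_len(n - 1))]
  nxt <- v[c(seq.int(2, n), 1)]
  sum(v > prev & v >= nxt & v > max(v) / 2)
}

# probability mass in a +/- hw window around a 0-based angle
angle_mass <- function(v, centre, hw = 10) {
  sum(v[((centre + (-hw:hw)) %% 360) + 1])
}

# full canonical scan for a two-source scene; returns scan + metrics
run_standard <- function(sources, seed = 1, frames_per_pose = 12,
                         noise = 0.1) {
  sc <- scene_spec(sources, background_noise_level = noise,
                   duration_frames = 10 * frames_per_pose, seed = seed)
  scan <- run_scan(sc, default_geom, default_fb,
                   frames_per_pose = frames_per_pose)
  truth <- vapply(sources, `[[`, numeric(1), "azimuth_deg")
  targets <- if (length(sources) == 2)
    reference_spectra(sc, default_geom, default_fb) else NULL
  list(scan = scan, metrics = scan_metrics(scan, truth, targets),
       truth = truth)
}
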