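---
title: "Active binaural mapping: model, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Active binaural mapping: model, parameters, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem and the model

A pair of microphones on a rotating head hears a mixture of sound
sources. The interaural time difference (ITD) of a plane wave from
egocentric azimuth $\psi$ is $\tau = (d/c)\sin\psi$, with microphone
spacing $d$ and speed of sound $c$. Two well-known ambiguities make a
single binaural observation insufficient: mirror positions across the
interaural axis produce identical ITDs (front/back confusion), and
whenever $d$ exceeds half the wavelength several delays explain the same
phase (spatial aliasing), so high-frequency sources produce phantom
images. `earmap` implements an *active hearing* analyzer that resolves
both ambiguities by rotating the head and accumulating evidence in a
world-centred probability map, using ITD as the only spatial cue.

The processing chain per 4096-sample stereo frame is:

1. **Cochlear decomposition.** A bank of 4th-order gammatone filters
   (default 50 linearly spaced centre frequencies, 100-5000 Hz,
   bandwidth $1.019\,\mathrm{ERB}(f_c)$ with
   $\mathrm{ERB}(f) = 24.7(4.37f/1000+1)$) splits each channel into
   band signals.
2. **EPSP transform.** Each band signal is reduced to its positive-going
   zero crossings; unit impulses at the crossings are convolved with a
   Gaussian pulse, mimicking the stereotyped, phase-locked excitatory
   postsynaptic potentials that drive brainstem coincidence detectors.
   The result keeps timing and discards amplitude (the transform is
   invariant to positive rescaling of its input).
3. **Delay-and-sum beamforming.** For every whole-sample interaural lag
   $k = -K,\dots,K$ with $K = \lfloor d f_s / c \rfloor$ (41 beams for
   the default rig), one channel is time-shifted against the other and
   the two are averaged; beam angles are
   $\theta_b = \arcsin(c T_b / d)$. The frame RMS of each beam gives a
   bands-by-beams egocentric energy image $S_{f,b}$. The closed-form
   narrow-band response
   $A(\psi,\theta) = \sqrt{2 + 2\cos(2\pi f d(\sin\psi - \sin\theta)/c)}/2$
   serves as an independent oracle for this stage.
4. **Evidence construction.** Each band row of $S$ is interpolated from
   the non-uniform beam angles onto whole degrees in $[-90, 90]$ by a
   natural cubic spline, mirrored across the interaural axis onto the
   back half circle (value at $180^\circ - \alpha$ equals the value at
   $\alpha$), and normalized so each band sums to one. Normalization
   within bands is the competitive step that lets a single location win
   a band.
5. **Recursive Bayesian fusion.** The evidence is rotated by the head
   orientation into world coordinates (an exact circular shift on the
   1-degree grid) and multiplied into the allocentric prior map, band by
   band; each band row is renormalized after every update. A stationary
   source reinforces the same world angle at every head pose while its
   phantom and mirror images wander, so the product collapses onto the
   true location.

# Coordinate and sign conventions

Azimuths are degrees in a fixed world frame; $0^\circ$ is the frontal
midline at head orientation $0^\circ$ and angles increase to the right.
Positive ITD means the sound arrives at the right microphone first; in
the beamformer, positive lags advance the left channel. The allocentric
grid has 360 one-degree cells; head orientations are integer degrees so
rotation is an exact shift and conserves probability to machine
precision.

# Tunable parameters

| parameter | default | units | role |
|---|---|---|---|
| `mic_spacing_m` | 0.145 | m | rig geometry; sets $K$ and the beam count $2K+1$ |
| `speed_of_sound_mps` | 343 | m/s | not a measured rig property; configurable |
| `sample_rate_hz` | 48000 | Hz | capture rate; delays are quantized to $1/f_s$ |
| `frame_length` | 4096 | samples | analysis buffer (~85 ms) |
| `n_bands`, range | 50, 100-5000 | Hz | gammatone bank (linear or ERB spacing) |
| `epsp_width_ms` | 1 | ms | total duration of the EPSP pulse (support $\pm 3\sigma$, so $\sigma \approx 0.17$ ms) |
| `schedule` | 0,20,...,180 | deg | head poses; 10 poses = 9 rotations |
| `frames_per_pose` | 12 | frames | ~1 s of audio per pose |
| `background_noise_level` | 0.1 | linear RMS | diffuse, interaurally uncorrelated floor relative to unit-RMS sources (~20 dB SNR, a quiet room) |

# Design choices in detail

**EPSP pulse width.** `epsp_width_ms` is the pulse's *total duration*,
not its width at half maximum. The distinction matters: a Gaussian whose
half-maximum width is a full millisecond attenuates the fundamental of a
2400 Hz pulse train by a factor $e^{-20}$, which removes every trace of
beam structure above roughly 1 kHz - precisely the regime whose
disambiguation is the point of the method. With a 1 ms total duration
($\sigma = 1/6$ ms), audio-domain beam profiles correlate with the
analytic response $A$ at 0.94-1.00 across 500-2400 Hz while still
smoothing crossing jitter. Millisecond-scale total duration matches the
brainstem EPSPs the transform emulates.

**AC-coupled coincidence stage.** Channel means are removed per band and
frame before delay-and-sum. Overlapping EPSP pulses carry a DC pedestal
that holds no interaural timing information yet inflates every beam's
RMS equally; left in place it caps the relative depth of high-frequency
beam profiles at a few percent and the multiplicative fusion can no
longer suppress phantom lobes within nine rotations. With the mean
removed, a 2400 Hz tone's beam profile shows near-complete nulls and the
ambiguity collapses as intended. Physiologically this is the statement
that coincidence detectors respond to coincidences, not to standing
depolarization.

**Circular beam shifts.** Shifts within a frame wrap around rather than
zero-fill. Zero-filling loses up to $K$ samples on the outer beams,
a systematic, lag-dependent energy bias of ~0.25% that is *larger* than
the genuine high-frequency beam modulation and visibly corrupts the
match to the analytic oracle. Wrapping keeps every beam's energy
estimate unbiased at the cost of one discontinuous sample, negligible
for the quasi-stationary signals the analyzer consumes.

**Per-frame recursive updates.** Every 4096-sample frame contributes one
multiplicative update (`frame_fusion = "multiply"`), as in a real-time
system that folds in each incoming buffer. Averaging the 12 frames of a
pose into a single evidence map before updating (`"average"`) is
available as an option, but nine averaged updates leave the per-band
posteriors tens of degrees wide: two sources 11 degrees apart then merge
into one peak and the estimated source spectra degrade rather than
improve with rotation. With per-frame updates the same scene yields two
distinct peaks at the true azimuths and a spectral correlation that
rises over rotations.

**Renormalized recursion.** The raw running product of per-band
probabilities underflows after a few dozen updates, so each band row is
renormalized after every multiplication; this changes neither the
per-band argmax nor the ratios between peaks. Entries are floored at
$10^{-12}$ first, so no angle can be permanently vetoed by a single
zero, and fusing the same evidence in any order gives the same map to
within $10^{-9}$.

**Numerical details.** The asin argument of the beam-angle map is
clamped to $[-1,1]$ to absorb floating-point excess. Natural-spline
resampling is applied as a cached linear operator (the interpolation is
linear in the data), and negative interpolation artifacts are clipped to
a small positive epsilon. Peak finding works on the circular profile
with topographic prominence; ties break toward the smaller angle; the
global maximum's prominence is its height above the global minimum.
Peak extents are half-prominence arcs truncated at the circular midpoint
towards the other reported peak. Zero crossings are assigned to the
later sample with no sub-sample interpolation. Fractional interaural
delays in the *simulator* are exact for tones (closed-form evaluation)
and windowed-sinc interpolated for stochastic sources - the world is
never quantized to whole samples, only the analyzer is.

# What the simulator does and does not emulate

The scene generator renders stationary point sources (pure tones, tone
complexes, broadband noise, user WAV files) at fixed world azimuths into
two channels whose only spatial cue is the ITD, plus an interaurally
uncorrelated Gaussian background. It reproduces the geometry the
analyzer assumes: free-field plane waves, no reverberation, no
interaural level differences, no pinna filtering, no source motion, no
microphone directivity. Passing tests therefore demonstrate the
*algorithmic* claims - ambiguity collapse, spectral-spatial resolution,
convergence over rotations - under the cue model the method is designed
for; they do not certify performance in reverberant rooms or with
moving sources, where allocentrically non-stationary energy is
deliberately blurred by the fusion.

# Quantification

Localization error sums, over true sources, the circular distance from
each source to the nearest of the two most prominent peaks of the
frequency-collapsed map. Spectral correlation is the Pearson correlation
between the difference of the two true source spectra (each source's
clean waveform through the same filter bank) and the difference of the
per-band map mass inside the two peaks' half-prominence extents; it is a
probability-mass analogue of a power spectrum, not a calibrated power
estimate. Peak width is the half-prominence arc length in degrees.

# Problem sizes

The shipped test suite exercises full 10-pose, 12-frames-per-pose scans
(the canonical scenario) for the end-to-end behavioural checks and
smaller 2-4 pose scans for interface and invariant tests; the
acceptance script runs the canonical tone-in-noise scenario over five
seeds, about 15 s per scan on a single core.

# Known limitations

* Resolution at low frequencies is limited by beam width: a 300 Hz tone
  11 degrees from broadband noise merges with it, and in this
  implementation the merge persists at 22 degrees - the tone's two-band
  vote remains a shoulder on the noise peak's flank rather than a
  distinct maximum. The EPSP pulse wide enough to keep low-frequency
  beam profiles faithful to the analytic response suppresses the
  high-band fine structure that would thin those flanks; the two
  desiderata trade off through the single kernel width.
* ITDs carried by envelopes of high-frequency sounds are exploited only
  implicitly (through crossing-rate fluctuations), and interaural level
  differences not at all.
* Sources coherent in both frequency and time fuse into a single image;
  there is no mechanism for discounting unreliable time-frequency
  regions.
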