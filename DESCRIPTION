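Package: earmap
Title: Binaural Auditory Scene Analysis by Active Head Rotation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates a rotating two-microphone array and resolves the
    surrounding acoustic scene in both space and frequency using only the
    interaural time difference (ITD) cue. Stereo frames are decomposed by a
    gammatone filter bank, converted to phase-locked EPSP-like pulse trains,
    scanned by banks of frequency-tuned delay-and-sum beamformers, and the
    resulting egocentric spectral-spatial evidence is fused across head
    rotations into a 360-degree allocentric probability map by a recursive
    Bayesian update. Includes a binaural scene simulator (tones, tone
    complexes, broadband noise, WAV stimuli), localization and spectral
    resolution metrics, and an experiment runner with a command-line
    interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    yaml
Suggests:
    signal,
    jsonlite,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
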