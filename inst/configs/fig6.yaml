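# Two interleaved tone complexes separated by 22 deg: components every
# 600 Hz, starting at 200 Hz and 500 Hz respectively.
geometry: {mic_spacing_m: 0.145, speed_of_sound_mps: 343, sample_rate_hz: 48000}
filterbank: {n_bands: 50, f_low_hz: 100, f_high_hz: 5000, spacing: linear}
frame_length: 4096
frames_per_pose: 12
schedule: {from: 0, to: 180, by: 20}
background_noise_level: 0.1
seed: 1
sources:
  - {kind: tone_complex, azimuth_deg: 0, level: 1,
     freqs_hz: [200, 800, 1400, 2000, 2600, 3200, 3800, 4400]}
  - {kind: tone_complex, azimuth_deg: 22, level: 1,
     freqs_hz: [500, 1100, 1700, 2300, 2900, 3500, 4100, 4700]}
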