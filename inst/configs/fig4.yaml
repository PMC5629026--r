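# Broadband noise at 0 deg and a 2400 Hz tone at 11 deg, canonical
# 0:20:180 scan. The scenario behind the tone-in-noise resolution figures.
geometry: {mic_spacing_m: 0.145, speed_of_sound_mps: 343, sample_rate_hz: 48000}
filterbank: {n_bands: 50, f_low_hz: 100, f_high_hz: 5000, spacing: linear}
frame_length: 4096
frames_per_pose: 12
schedule: {from: 0, to: 180, by: 20}
background_noise_level: 0.1
seed: 1
sources:
  - {kind: broadband_noise, azimuth_deg: 0, level: 1}
  - {kind: tone, azimuth_deg: 11, freq_hz: 2400, level: 1}
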