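# Two-talker scene: supply your own mono WAV files (any rate; they are
# resampled to the run's sampling rate and looped if shorter than the
# run). Replace the paths below before running.
geometry: {mic_spacing_m: 0.145, speed_of_sound_mps: 343, sample_rate_hz: 48000}
filterbank: {n_bands: 50, f_low_hz: 100, f_high_hz: 5000, spacing: linear}
frame_length: 4096
frames_per_pose: 12
schedule: {from: 0, to: 180, by: 20}
background_noise_level: 0.1
seed: 1
sources:
  - {kind: wav_file, azimuth_deg: 0,  level: 1, path: talker_female.wav}
  - {kind: wav_file, azimuth_deg: 45, level: 1, path: talker_male.wav}
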