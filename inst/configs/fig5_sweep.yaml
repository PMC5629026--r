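# Template for the tone-in-noise frequency sweep: sources are replaced
# cell by cell by the sweep (noise at 0 deg, tone at each separation).
# Run e.g.:
#   earmap sweep --config fig5_sweep.yaml \
#     --frequencies 300,600,1200,2400,4800 --separations 11,22
geometry: {mic_spacing_m: 0.145, speed_of_sound_mps: 343, sample_rate_hz: 48000}
filterbank: {n_bands: 50, f_low_hz: 100, f_high_hz: 5000, spacing: linear}
frame_length: 4096
frames_per_pose: 12
schedule: {from: 0, to: 180, by: 20}
background_noise_level: 0.1
seed: 1
sources: []
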