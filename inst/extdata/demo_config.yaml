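# Demo experiment: one chromosomal locus and one cytosolic aggregate
# marker, a control and three treatments whose simulated mobility scales
# inversely with their crowding change. Small sizes so the full pipeline
# runs in well under a minute.
seed: 1
output_dir: "crowdmsd-demo"
experiment:
  treatment_times: [30, 60]
  n_replicates: 3
  markers:
    Ori2: {amplitude: 0.001593, hurst: 0.2}
    muNS: {amplitude: 0.031850, hurst: 0.2}
  conditions:
    control:       {mobility_scale: 1.000, crowding_scale: 1.00}
    ciprofloxacin: {mobility_scale: 1.111, crowding_scale: 0.90}
    rifampicin:    {mobility_scale: 1.053, crowding_scale: 0.95}
    sorbitol:      {mobility_scale: 0.769, crowding_scale: 1.30}
simulation:
  n_tracks: 12
  n_frames: 150
  frame_interval: 0.1
  loc_noise_sigma: 0.0
msd:
  target_lag_s: 10
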