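# Example end-to-end run: one MGV well (74 Pa, 0.4 nM) imaged with a
# 5 Hz, 30 mT sinusoidal drive; 500-frame loops at 500 Hz.
session: example
seed: 1
phantom:
  grid_shape: [32, 32]
  pixel_pitch: 0.1
  background_echogenicity: 1.0
  wells:
    - center: [16, 16]
      half_size: [5, 5]
      elastic_modulus: 74.0     # Pa
      concentration: 0.4        # nM
      agent: MGV
acquisition:
  frame_rate: 500               # Hz
  n_frames: 500
  f0: 5                         # Hz
  field_strength: 30            # mT
  center_freq: 15.6             # MHz
  sound_speed: 1540             # m/s
  n_loops: 4
  noise_sd: 0.05
  coupling_kappa: 1.0
rois:
  - {label: well, x0: 10, z0: 10, x1: 22, z1: 22}
  - {label: background, x0: 0, z0: 0, x1: 32, z1: 8}
pairings:
  - {sample: well, background: background}
options:
  reject_loops: false
  decimals: 1
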