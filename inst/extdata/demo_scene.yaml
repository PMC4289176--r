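# Demo synthetic scene: a migrating granule neuron with two-stroke organelle
# motion, an actin hotspot, lab-frame adhesion puncta and shot + read noise.
scene:
  n_frames: 6
  n_z: 9
  n_y: 40
  n_x: 160
  voxel_z_um: 1
  frame_interval_s: 120
  soma_radius_um: 3
  process_length_um: 14
  nucleus_speed_um_s: 0.02
  lead_amplitude_um: 4
  cycle_period_s: 480
  hotspot_amplitude: 120
  hotspot_sigma_um: 1.5
  start_x_um: 10
  adhesion_x_um: [15, 19, 23]
  gaussian_noise_sd: 2
  poisson_noise: true
  seed: 7
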