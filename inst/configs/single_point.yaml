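# Single-point phantom, desk-scale configuration: 32x32 grid over 8 cm
# radius, 64 frequency bins 0.1-4.8 GHz, 90 turntable positions, water medium.
seed: 1
geometry:
  ring_radius_m: 0.085
  opening_angle_deg: 0
  container_radius_m: 0.085
sweep:
  f_start_hz: 100.0e+6
  f_stop_hz: 4.8e+9
  n_points: 64
rotation:
  n_positions: 90
medium:
  eps_r: 80
grid:
  n_side: 32
  radius_m: 0.08
phantom:
  kind: single_point
  radius_m: 0.06
  azimuth_deg: 180
solver:
  window: hann
  gain_model: isotropic
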