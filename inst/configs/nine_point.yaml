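# Nine-point phantom at the same desk-scale acquisition.
seed: 1
geometry:
  ring_radius_m: 0.085
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
  kind: nine_point
  r_x_m: 0.07
  r_y_m: 0.06
  r_diag_m: 0.045
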