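geometry:
  periderm_height: 2.0
  periderm_base_radius: 0.3
  aperture_radius: 0.18
  insertion_depth: 0.18
  subumbrella_height: 0.7
  subumbrella_max_radius: 0.12
  opening_radius: 0.05
  ridge_amplitude: 0.0
  ridge_count: 6
  taper_exponent: 1.2
  belly_fraction: 0.55
  min_clearance: 0.05
  min_opening: 0.02
motion:
  T_exp: 1.0
  T_con: 1.0
  peak_fraction_exp: 0.6
  peak_fraction_con: 0.5
  amplitude_scale: 0.45
  amplitude_control_points: ~
fluid:
  density: 1000.0
  viscosity: 0.001
solver:
  eta: 1.0e-08
  tol: 1.0e-09
  max_uzawa: 30.0
  grad_div: 10000.0
  penal_error_max: 0.01
grid:
  radius_extent: 5.0
  height_extent: 10.0
  nr: 120
  nz: 240
snapshot_interval: 0.05
cut_points:
  z_min: 2.05
  z_max: 2.5
  spacing: 0.05
  r: 0.0
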