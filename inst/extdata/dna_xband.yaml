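# Shipped defaults: B-form DNA duplex labelled 9 bp apart, X-band PELDOR.
helix:
  form: B
  n_bp: 20
  rise_A: 3.38
  twist_deg: 36.0
labels:
  i: 1
  j: 10
  radial_A: 9.0
  tangent_A: 0.0
  axial_A: 3.18
  tilt_deg: 36.6
  twist_deg: 0.0
  spin_deg: 0.0
fluct:
  sigma_r_nm: 0.287    # FWHM 0.675 nm / 2.355
  wobble_deg: 15.0
weights:
  ss: 0.25
  sa: 0.25
  as: 0.25
  aa: 0.25
band: X
offsets: [40, 55, 70, 85]
n_models: 500
seed: 42
pulses:
  pump_ns: 20
  probe_half_ns: 32
  probe_pi_ns: 32
spin:
  g: [2.0088, 2.0065, 2.0027]
  A_MHz: [15, 15, 98]
grids:
  t_max_us: 1.8
  t_step_us: 0.02
  r_min_nm: 1.5
  r_max_nm: 8.0
  r_step_nm: 0.02
  n_orient: 3000
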