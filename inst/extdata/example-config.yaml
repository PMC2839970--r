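# Example planning run: two 1 mm diameter cylindrical needle electrodes at
# 1 cm center separation in homogeneous tissue (0.42 S/m), swept over the
# dimensionless voltages C = 0.5, 1.5, 2.5 and pulse numbers 10, 50, 100.
# Model parameters are the illustrative 100 us preset
# (see ?default_illustrative_model); replace with a fitted model file via
#   model: {path: fitted-model.json}
geometry:
  units: mm
  separation: 10        # center-to-center distance L
  radii: [0.5, 0.5]     # 1 mm diameter needles
  conductivity: 0.42    # S/m
protocol:
  n_pulses: [10, 50, 100]
  C: [0.5, 1.5, 2.5]
  pulse_length_s: [1.0e-4]
model:
  Eco: 1.5e+5           # V/m
  k1: 0.03              # per pulse
  Ao: 4.0e+4            # V/m
  k2: 0.03              # per pulse
  pulse_length_s: 1.0e-4
numerics:
  h: 0.01               # grid spacing, units of L
  tol: 1.0e-8
  s_kill: 0.05
  s_live: 0.95
output:
  dir: ireplan-out
  formats: [csv, vtk]
seed: 1
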