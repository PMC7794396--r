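schema: 1
package_version: 1.0.0
seed: 1
membrane:
  m0: 3.2e-11
  K0: 1.0
  x_ref: 0.007
  m_ref: 6.5e-11
  K_ref: 0.03
  l_m: 0.0098779
  l_K: 0.0019963
  A: 1.488e-09
  xi_by_spl:
    '60': 1.0e-08
    '80': 5.0e-07
    '100': 2.0e-06
fluid:
  rho0: 1000.0
  nu: 1.0e-06
geometry:
  L: 0.002
  h: 0.0004
  helicotrema_len: 0.0004
  Nx: 40
  Ny: 58
  dx: 5.0e-05
stimulus:
  '1':
    f: 20000.0
    spl: 80.0
    phase: 0.0
particle:
  diameter: 2.0e-07
  density: 1000.0
  restitution: 0.95
  friction: 0.001
  count: 5000
solver:
  steps_per_cycle: 64
  n_cycles: 12
  transient_cycles: 5
  courant_cap: 0.9
  theta: 0.5
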