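model: region_II
t_end: 900.0
protocol:
  kind: none
domain:
  'N': 20.0
integrator:
  rtol: 1.0e-07
  atol: 1.0e-09
  sigma: 0.0
  dt: 0.01
  seed: 1.0
analysis: landscape
preset: landscape_regionII

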