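# Example pfmsim run configuration.  Any omitted key falls back to the
# package defaults (published muscle dimensions and material constants).
geometry:
  length: 70
  width: 60
  height: 40
material:
  young_modulus: 0.2
  poisson_ratio: 0.4
  density: 1.12e-9
sphere:
  diameter: 90
  density: 7.86e-9
  gap: 23
contact:
  friction_coefficient: 0.03
simulation:
  duration: 0.15
  snapshot_interval: 0.03
mesh:
  target_edge: 3
  fixed_edges: xmin
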