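# 22-cell hepatocyte disc monolayer, centre seed, with mechanics
tissue:
  kind: disc
  n_cells: 22
  cell_diameter: 21
  spacing_factor: 0.85
rule:
  kind: contact
  contact_slack: 0.01
seeds: centre
protocol:
  T0: 272.15
  B: 100
  T_end: 230
mc:
  alpha: 10.4
  replicates: 100
  rng_seed: 1
  method: gillespie
mech:
  c_adh: 30
  c_rep: 750
  adh_reach: 1.25
  dt_mech: 0.001
stages: [propagation, mechanics]
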