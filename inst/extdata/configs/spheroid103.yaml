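# 103-cell hepatocyte spheroid (~100 um), border seed
tissue:
  kind: spheroid
  target_cells: 103
  spheroid_diameter: 100
  cell_diameter: 21
rule:
  kind: contact
  contact_slack: 0.01
seeds: corner
protocol:
  T0: 272.15
  B: 100
  T_end: 230
mc:
  alpha: 10.4
  replicates: 100
  rng_seed: 1
  method: gillespie
stages: [propagation]
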