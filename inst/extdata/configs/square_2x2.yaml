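# 2 x 2 validation construct: propagation only, natural tau horizon
tissue:
  kind: square_2x2
  cell_diameter: 21
rule:
  kind: contact
  contact_slack: 0.5    # every pair including the diagonal is a neighbour
protocol:
  T0: 272.15
  B: 100
  T_end: 230
mc:
  alpha: 10.4
  epsilon: 0.05
  replicates: 1000
  rng_seed: 1
  method: fixed_step
stages: [propagation]
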