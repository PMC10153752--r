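# Single 20 cM CEN8-THR1 interval on chromosome VIII, as used by the
# spore-autonomous fluorescence assay.
markers:
  - {name: CEN8, chromosome: VIII, position_cM: 0.0}
  - {name: THR1, chromosome: VIII, position_cM: 20.0}
n_tetrads: 1000
nu: 1
p2: 0
p_death: 0
p_ndj: 0
seed: 1
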