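# Five-marker chromosome XV map spanning URA3..HIS3, with illustrative
# interval lengths consistent with a wild-type total of 104.9 cM.
markers:
  - {name: URA3, chromosome: XV, position_cM: 0.0}
  - {name: LEU2, chromosome: XV, position_cM: 20.4}
  - {name: LYS2, chromosome: XV, position_cM: 41.4}
  - {name: ADE2, chromosome: XV, position_cM: 77.3}
  - {name: HIS3, chromosome: XV, position_cM: 104.9}
n_tetrads: 1000
nu: 1
p2: 0
p_death: 0
p_ndj: 0
seed: 1
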