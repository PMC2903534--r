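# Desk-scale power-study configuration: 30x30 homogeneous lattice,
# all three statistics under both weight schemes.
geography:
  lattice:
    rows: 30
    cols: 30
    population_per_cell: 5000
patterns:
  - type: local
    fraction: 0.05
    rr: 1.5
  - type: local
    fraction: 0.10
    rr: 1.5
  - type: local
    fraction: 0.20
    rr: 1.5
  - type: local
    fraction: 0.30
    rr: 1.5
  - type: spiral
    core_fraction: 0.02
    rr: 1.5
  - type: linear
    rr: 1.5
statistics: [I_w, I, I_pop]
schemes: [Adj, PD]
M: 2000
R: 500
alpha: 0.05
seed: 1
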