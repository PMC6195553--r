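# Example run configuration: moderate-affinity reversible gel with one
# binding tracer.  All omitted keys resolve to the package defaults.
schema: geldiff-config/1
seed: 1
energies:
  E_c: -10.0
  E_b: -5.0
  T_fc: 0.0
  T_cb: -5.0
  T_bf: 0.0
gel:
  stars_per_side: 4
  d: 2
sim:
  steps: 100000
  sample_every: 200
particles:
  n_binding: 1
  n_nonbinding: 0
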