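# Sirolimus (rapamycin): CYP3A4 and P-gp substrate, long half-life.
schema: 1
name: sirolimus
mw: 914.2
logp: 4.3
fu: 0.04
blood_plasma_ratio: 30
absorption:
  model: first_order
  ka: 0.3
  fraction_dissolvable: 0.2
pathways:
- enzyme: CYP3A4
  type: linear
  clint_specific: 1.7147e6  # ~800 L/h
- enzyme: P-gp
  type: linear
  clint_specific: 7.4074e5  # ~80 L/h
renal_clearance: 0.0
interactions: []
therapeutic_window:
  metric: Cmin
  lower: 3
  upper: 8
  unit: ng/mL
  interval: trough at steady state
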