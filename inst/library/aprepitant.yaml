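# Aprepitant: NK1 antagonist, CYP3A4-dominant clearance; weak-to-moderate
# CYP3A4 inhibitor and mild CYP3A4/CYP2C9 inducer.
schema: 1
name: aprepitant
mw: 534.4
logp: 4.5
fu: 0.05
blood_plasma_ratio: 1.0
absorption:
  model: first_order
  ka: 0.5
  fraction_dissolvable: 0.65
pathways:
- enzyme: CYP3A4
  type: linear
  clint_specific: 1.5003e5  # ~70 L/h
- enzyme: CYP1A2
  type: linear
  clint_specific: 2.572e4   # ~5 L/h
- enzyme: CYP2C19
  type: linear
  clint_specific: 3.655e4   # ~3 L/h
renal_clearance: 0.0
interactions:
- target: CYP3A4
  mechanism: inhibition
  type: competitive
  ki: 1.0
- target: CYP3A4
  mechanism: induction
  emax: 0.3
  ec50: 0.5
- target: CYP2C9
  mechanism: induction
  emax: 0.4
  ec50: 0.5
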