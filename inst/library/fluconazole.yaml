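# Fluconazole: cleared mainly by renal excretion; moderate-to-strong
# competitive inhibitor of CYP2C19/CYP2C9/CYP3A4.
schema: 1
name: fluconazole
mw: 306.3
logp: 0.4
fu: 0.89
blood_plasma_ratio: 1.0
absorption:
  model: first_order
  ka: 1.5
  fraction_dissolvable: 0.95
pathways:
- enzyme: CYP3A4
  type: linear
  clint_specific: 643.0     # ~0.3 L/h minor oxidative pathway
renal_clearance: 0.9        # L/h, dominant route
interactions:
- target: CYP2C19
  mechanism: inhibition
  type: competitive
  ki: 10.0
- target: CYP2C9
  mechanism: inhibition
  type: competitive
  ki: 20.0
- target: CYP3A4
  mechanism: inhibition
  type: competitive
  ki: 25.0
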