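# Voriconazole: CYP2C19-dominant azole (genotype-sensitive exposure),
# mechanism-based CYP3A4 inactivator and competitive CYP2C19 inhibitor.
schema: 1
name: voriconazole
mw: 349.3
logp: 1.0
fu: 0.42
blood_plasma_ratio: 1.0
absorption:
  model: first_order
  ka: 1.1
  fraction_dissolvable: 0.9
pathways:
- enzyme: CYP2C19
  type: linear
  clint_specific: 3.0458e5  # ~25 L/h in CYP2C19 NM
- enzyme: CYP2C9
  type: linear
  clint_specific: 1.929e4   # ~8 L/h
- enzyme: CYP3A4
  type: linear
  clint_specific: 1.0717e4  # ~5 L/h
renal_clearance: 0.0
interactions:
- target: CYP3A4
  mechanism: inhibition
  type: irreversible
  kinact: 0.1       # 1/h
  ki_half: 10.0     # umol/L
- target: CYP2C19
  mechanism: inhibition
  type: competitive
  ki: 5.0
- target: CYP2C9
  mechanism: inhibition
  type: competitive
  ki: 8.0
therapeutic_window:
  metric: Cmin
  lower: 1
  upper: 5
  unit: ug/mL
  interval: trough at steady state
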