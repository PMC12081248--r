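# Tacrolimus: CYP3A4/CYP3A5 substrate (CYP3A5 genotype-sensitive),
# mechanism-based CYP3A4 inactivator. Literature-typical fixtures.
schema: 1
name: tacrolimus
mw: 804.0
logp: 3.3
fu: 0.01
blood_plasma_ratio: 15      # extensive erythrocyte partitioning
absorption:
  model: first_order
  ka: 1.0
  fraction_dissolvable: 0.25
pathways:
- enzyme: CYP3A4
  type: linear
  clint_specific: 1.0717e7  # ~5000 L/h at reference expression
- enzyme: CYP3A5
  type: linear
  clint_specific: 2.0425e7  # ~1500 L/h in CYP3A5 expressers (E0 0.68)
renal_clearance: 0.0
interactions:
- target: CYP3A4
  mechanism: inhibition
  type: irreversible
  kinact: 0.04      # 1/h
  ki_half: 0.39     # umol/L (KI)
- target: CYP3A5
  mechanism: inhibition
  type: competitive
  ki: 1.0
therapeutic_window:
  metric: Cmin
  lower: 5
  upper: 15
  unit: ng/mL
  interval: trough at steady state
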