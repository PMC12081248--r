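# Busulfan: alkylating conditioning agent, cleared by glutathione conjugation
# (GSTA1); exposure monitored as AUC per 6-h dosing interval in uM*min.
# GSTA1 carries a childhood ontogeny factor in the enzyme registry.
schema: 1
name: busulfan
mw: 246.3
logp: -0.52
fu: 0.68
blood_plasma_ratio: 1.0
absorption:
  model: first_order
  ka: 1.2
  fraction_dissolvable: 0.95
pathways:
- enzyme: GSTA1
  type: linear
  clint_specific: 2.037e4   # ~22 L/h whole-liver in adults
renal_clearance: 0.0
interactions: []
therapeutic_window:
  metric: AUC
  lower: 900
  upper: 1350
  unit: uM.min
  interval: per 6-h dosing interval at steady state
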