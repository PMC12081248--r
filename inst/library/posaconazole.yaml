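# Posaconazole: UGT1A4-cleared azole; suspension shows strong positive food
# effect (fed exposure 2.5-3x) captured by fed-state modifiers on the
# Weibull dissolution; tablet formulation is food-insensitive.
schema: 1
name: posaconazole
mw: 700.8
logp: 4.0
fu: 0.02
blood_plasma_ratio: 1.0
absorption:            # oral suspension, fasted reference
  model: weibull
  shape: 1.3
  scale: 3.0           # h
  ka: 0.6
  fraction_dissolvable: 0.3
  fed:
    dissolution_scale: 0.5
    bioavailable_fraction: 2.75
formulations:
  tablet:
    model: first_order
    ka: 0.8
    fraction_dissolvable: 0.9
pathways:
- enzyme: UGT1A4
  type: linear
  clint_specific: 4.2438e6  # ~550 L/h
renal_clearance: 0.0
interactions:
- target: CYP3A4
  mechanism: inhibition
  type: competitive
  ki: 0.05          # umol/L unbound (potent CYP3A inhibitor)
- target: P-gp
  mechanism: inhibition
  type: competitive
  ki: 1.0
therapeutic_window:
  metric: Cmin
  lower: 0.7
  upper: null        # no upper bound
  unit: ug/mL
  interval: trough at steady state
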