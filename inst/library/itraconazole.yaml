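# Itraconazole: CYP3A4 substrate and very potent competitive CYP3A4
# inhibitor; highly bound, lipophilic. logp here is the effective
# partitioning lipophilicity used by the Kp method.
schema: 1
name: itraconazole
mw: 705.6
logp: 4.5
fu: 0.004
blood_plasma_ratio: 1.0
absorption:
  model: first_order
  ka: 0.3
  fraction_dissolvable: 0.55
pathways:
- enzyme: CYP3A4
  type: linear
  clint_specific: 1.3932e7  # ~6500 L/h
renal_clearance: 0.0
interactions:
- target: CYP3A4
  mechanism: inhibition
  type: competitive
  ki: 0.0013        # umol/L unbound (nM-potency)
- target: P-gp
  mechanism: inhibition
  type: competitive
  ki: 0.1
- target: BCRP
  mechanism: inhibition
  type: competitive
  ki: 0.5
therapeutic_window:
  metric: Cmin
  lower: 0.5
  upper: null
  unit: ug/mL
  interval: trough at steady state
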