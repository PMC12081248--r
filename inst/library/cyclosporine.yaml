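# Cyclosporine: calcineurin inhibitor, CYP3A/P-gp substrate and inhibitor.
# Values are curated literature-typical estimates (in vitro CLint scaled to
# whole liver; Ki on the unbound-plasma scale); see the methods vignette.
schema: 1
name: cyclosporine
mw: 1202.6          # g/mol
logp: 2.9
fu: 0.07
blood_plasma_ratio: 1.36
absorption:
  model: first_order
  ka: 0.7           # 1/h
  fraction_dissolvable: 0.5
pathways:
- enzyme: CYP3A4
  type: linear
  clint_specific: 1.0717e6   # uL/min/umol; ~500 L/h whole-liver at reference expression
- enzyme: P-gp
  type: linear
  clint_specific: 4.6296e5   # biliary/efflux component, ~50 L/h
renal_clearance: 0.3         # L/h; renal excretion is minor
interactions:
- target: CYP3A4
  mechanism: inhibition
  type: competitive
  ki: 1.0           # umol/L unbound
- target: P-gp
  mechanism: inhibition
  type: competitive
  ki: 1.3
- target: OATP1B1
  mechanism: inhibition
  type: competitive
  ki: 0.5
- target: OATP1B3
  mechanism: inhibition
  type: competitive
  ki: 0.5
therapeutic_window:
  metric: Cmin
  lower: 200
  upper: 400
  unit: ng/mL
  interval: trough on day 6
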