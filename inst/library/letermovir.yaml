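# Letermovir: UGT1A1/1A3 and OATP1B-mediated hepatic uptake clearance;
# inhibits CYP3A and hepatic uptake/efflux transporters, induces CYP2C9/19.
schema: 1
name: letermovir
mw: 572.6
logp: 3.0
fu: 0.012
blood_plasma_ratio: 1.0
absorption:
  model: first_order
  ka: 1.0
  fraction_dissolvable: 0.9
pathways:
- enzyme: UGT1A1
  type: linear
  clint_specific: 6.944e5   # ~150 L/h
- enzyme: UGT1A3
  type: linear
  clint_specific: 4.6296e5  # ~50 L/h
- enzyme: OATP1B1
  type: linear
  clint_specific: 1.3889e6  # uptake component, ~300 L/h
- enzyme: CYP3A4
  type: linear
  clint_specific: 6.43e4    # ~30 L/h minor
renal_clearance: 0.0
interactions:
- target: CYP3A4
  mechanism: inhibition
  type: competitive
  ki: 0.6
- target: OATP1B1
  mechanism: inhibition
  type: competitive
  ki: 0.3
- target: OATP1B3
  mechanism: inhibition
  type: competitive
  ki: 0.3
- target: P-gp
  mechanism: inhibition
  type: competitive
  ki: 1.0
- target: BCRP
  mechanism: inhibition
  type: competitive
  ki: 0.5
- target: CYP2C9
  mechanism: induction
  emax: 0.5
  ec50: 1.0
- target: CYP2C19
  mechanism: induction
  emax: 0.6
  ec50: 1.0
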