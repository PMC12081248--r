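# Omeprazole: CYP2C19-dominant proton-pump inhibitor (enteric-coated ->
# Weibull release), mechanism-based CYP2C19 inactivator and moderate
# competitive CYP3A inhibitor.
schema: 1
name: omeprazole
mw: 345.4
logp: 2.2
fu: 0.05
blood_plasma_ratio: 1.0
absorption:
  model: weibull
  shape: 2.0
  scale: 0.8        # h (enteric-coat lag)
  ka: 1.5
  fraction_dissolvable: 0.85
pathways:
- enzyme: CYP2C19
  type: linear
  clint_specific: 1.0965e7  # ~900 L/h (high-extraction in CYP2C19 NM)
- enzyme: CYP3A4
  type: linear
  clint_specific: 5.3583e5  # ~250 L/h
renal_clearance: 0.0
interactions:
- target: CYP2C19
  mechanism: inhibition
  type: irreversible
  kinact: 2.0
  ki_half: 1.0
- target: CYP3A4
  mechanism: inhibition
  type: competitive
  ki: 40.0
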