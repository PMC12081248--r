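# Phenytoin: anticonvulsant with saturable CYP2C9 clearance (therapeutic
# concentrations sit near Km) and broad enzyme induction. Induction EC50 is
# on the unbound-plasma scale, set so that therapeutic unbound exposure
# (~2-4 uM) produces near-maximal induction, matching the strong-inducer
# phenotype; Emax values grade by pathway.
schema: 1
name: phenytoin
mw: 252.3
logp: 0.5   # effective partitioning lipophilicity, calibrated to the
            # observed distribution volume (~0.6 L/kg); the octanol-water
            # logP overpredicts tissue binding for this ionised acid
fu: 0.1
blood_plasma_ratio: 1.0
pka:
- value: 8.3
  type: acid
absorption:
  model: first_order
  ka: 0.8
  fraction_dissolvable: 0.9
pathways:
- enzyme: CYP2C9
  type: saturable
  vmax_specific: 0.08       # umol/min/umol enzyme -> uninduced Vmax ~33 umol/h;
                            # with autoinduction at steady state this yields
                            # therapeutic unbound exposure (~3 uM, ~8 ug/mL total)
                            # at 300 mg/day
  km: 3.0                   # umol/L unbound
- enzyme: CYP2C19
  type: linear
  clint_specific: 1.2183e4  # ~1 L/h minor pathway
renal_clearance: 0.0
interactions:
- target: CYP2C9
  mechanism: induction
  emax: 2.0
  ec50: 0.5
- target: CYP2C19
  mechanism: induction
  emax: 2.0
  ec50: 0.5
- target: CYP3A4
  mechanism: induction
  emax: 2.5
  ec50: 0.5
- target: UGT1A4
  mechanism: induction
  emax: 1.5
  ec50: 0.8
- target: GSTA1
  mechanism: induction
  emax: 1.0
  ec50: 1.0
therapeutic_window:
  metric: Cmin
  lower: 10
  upper: 20
  unit: ug/mL
  interval: trough at steady state (status epilepticus target)
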