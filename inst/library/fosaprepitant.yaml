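# Fosaprepitant: intravenous phosphoramide prodrug, converted rapidly and
# essentially completely to aprepitant (first-order, half-life ~5 min).
schema: 1
name: fosaprepitant
mw: 614.4
logp: 1.5
fu: 0.05
blood_plasma_ratio: 1.0
pathways: []
renal_clearance: 2.0        # minor direct elimination of intact prodrug
prodrug:
  target: aprepitant
  kconv: 8.3                # 1/h
interactions:
- target: CYP3A4
  mechanism: inhibition
  type: competitive
  ki: 10.0                  # weak direct CYP3A4 inhibition
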