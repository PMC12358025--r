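markers:
- Cp1
- Cp2
- Cp3
pattern_map:
  Cp1:
    '420': A
    280+140: B
  Cp2:
    '510': A
    350+160: B
  Cp3:
    '390': A
    240+150: B
type_map:
  A/A/A: Ia
  B/A/A: Ib
  A/B/A: Ic
  B/B/B: III
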