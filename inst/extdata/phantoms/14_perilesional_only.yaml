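name: 14_perilesional_only
shape:
- 64
- 64
- 64
spacing:
- 1.0
- 1.0
- 1.0
foci:
- centre:
  - 20.0
  - 44.0
  - 44.0
  r_necrotic: 0.0
  r_enhancing: 0.0
  r_oedema: 6.0
satellites: []
ground_truth:
  f1: n/a
  f2: n/a
  f4: none
  f5: 0%
  f6: 0%
  f7: 0%
  f9: n/a
  f11: n/a
  f14: 100%
  f19: no
  f20: no
  f21: no
  f22: no
  f23: no
  f24: no
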