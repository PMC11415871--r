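name: 15_mild_enhancement
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
  - 44.0
  - 44.0
  - 44.0
  r_necrotic: 0.0
  r_enhancing: 2.0
  r_oedema: 10.0
satellites: []
ground_truth:
  f1: frontal
  f2: right
  f4: mild
  f5: <5%
  f6: 0%
  f7: 0%
  f9: focal
  f11: solid
  f14: '>95%'
  f19: no
  f20: no
  f21: no
  f22: no
  f23: no
  f24: no
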