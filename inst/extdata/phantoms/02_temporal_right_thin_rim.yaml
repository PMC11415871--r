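name: 02_temporal_right_thin_rim
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
  - 45.0
  - 44.0
  - 20.0
  r_necrotic: 6.0
  r_enhancing: 8.0
  r_oedema: 11.0
satellites: []
ground_truth:
  f1: temporal
  f2: right
  f4: marked
  f5: 6-33%
  f6: 0%
  f7: 6-33%
  f9: focal
  f11: thin
  f14: 34-67%
  f19: no
  f20: no
  f21: no
  f22: no
  f23: no
  f24: no
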