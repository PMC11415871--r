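name: 04_occipital_right_nonenhancing
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
  - 20.0
  - 20.0
  r_necrotic: 5.0
  r_enhancing: 5.0
  r_oedema: 8.0
satellites: []
ground_truth:
  f1: occipital
  f2: right
  f4: none
  f5: 0%
  f6: 6-33%
  f7: 0%
  f9: focal
  f11: n/a
  f14: 68-95%
  f19: no
  f20: no
  f21: no
  f22: no
  f23: no
  f24: no
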