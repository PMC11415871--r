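name: 12_midline_nonenhancing
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
  - 32.5
  - 44.0
  - 44.0
  r_necrotic: 4.0
  r_enhancing: 6.0
  r_oedema: 8.0
satellites: []
ground_truth:
  f1: frontal
  f2: center/bilateral
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
  f22: yes
  f23: yes
  f24: no
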