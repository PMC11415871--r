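name: 16_brainstem_deep_wm
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
  - 32.5
  - 26.5
  r_necrotic: 0.0
  r_enhancing: 2.0
  r_oedema: 3.5
satellites: []
ground_truth:
  f1: brainstem
  f2: center/bilateral
  f4: marked
  f5: 6-33%
  f6: 0%
  f7: 0%
  f9: focal
  f11: solid
  f14: 68-95%
  f19: no
  f20: no
  f21: yes
  f22: no
  f23: yes
  f24: no
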