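name: 05_multifocal_bridged
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
  - 40.0
  - 40.0
  r_necrotic: 0.0
  r_enhancing: 4.0
  r_oedema: 9.0
- centre:
  - 20.0
  - 48.0
  - 48.0
  r_necrotic: 0.0
  r_enhancing: 4.0
  r_oedema: 9.0
satellites: []
ground_truth:
  f1: frontal
  f2: left
  f4: marked
  f5: 6-33%
  f6: 0%
  f7: 0%
  f9: multifocal
  f11: solid
  f14: 68-95%
  f19: no
  f20: no
  f21: no
  f22: no
  f23: no
  f24: no
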