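name: 13_empty
shape:
- 64
- 64
- 64
spacing:
- 1.0
- 1.0
- 1.0
foci: []
satellites: []
ground_truth:
  f1: n/a
  f2: n/a
  f4: n/a
  f5: n/a
  f6: n/a
  f7: n/a
  f9: n/a
  f11: n/a
  f14: n/a
  f19: no
  f20: no
  f21: no
  f22: no
  f23: no
  f24: no
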