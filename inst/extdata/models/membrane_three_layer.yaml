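name: membrane-three-layer
materials:
  chitin: {"n": 1.56, k: 0.0}
  pigment: {"n": 1.74, k: 0.010}
ambient: air
substrate: air
layers:
  - {material: chitin, thickness_nm: 436}
  - {material: pigment, thickness_nm: 194}
  - {material: chitin, thickness_nm: 412}
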