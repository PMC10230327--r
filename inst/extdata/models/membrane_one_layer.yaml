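name: membrane-one-layer
materials:
  chitin: {"n": 1.56, k: 0.0}
ambient: air
substrate: air
layers:
  - {material: chitin, thickness_nm: 1042}
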