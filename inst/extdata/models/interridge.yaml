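# Interridge scale model: microrib grating homogenized at line fill
# 62/(62+58) over the 225 nm chitin lower lamina.
name: interridge
materials:
  chitin: {"n": 1.56, k: 0.0}
  microrib_emt: {"n": 1.3194, k: 0.0}
ambient: air
substrate: air
layers:
  - {material: microrib_emt, thickness_nm: 45}
  - {material: chitin, thickness_nm: 225}
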