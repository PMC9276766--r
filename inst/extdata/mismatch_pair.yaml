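# Size- and density-mismatched rectangle pair: the wider, denser tissue
# displaces the narrower, sparser one after collision (analysed by the
# collision-mechanics functions, not by the shape simulator).
world: {width: 4000, height: 3000}
default_speed: 29.5
tissues:
  - id: 1
    shape: {kind: rectangle, center: [1000, 1500], width: 1000, height: 2000}
    density: 2600
    color: "#377eb8"
  - id: 2
    shape: {kind: rectangle, center: [2250, 1500], width: 500, height: 2000}
    density: 1800
    color: "#ff7f00"
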