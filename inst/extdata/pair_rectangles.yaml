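# Control collision: two equally sized rectangles with a 500 um gap.
# With equal speeds the healed boundary is a straight line at the gap midline.
world: {width: 4000, height: 3000}
default_speed: 29.5
tissues:
  - id: 1
    shape: {kind: rectangle, center: [1000, 1500], width: 1000, height: 2000}
    color: "#4daf4a"
  - id: 2
    shape: {kind: rectangle, center: [2500, 1500], width: 1000, height: 2000}
    color: "#e41a1c"
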