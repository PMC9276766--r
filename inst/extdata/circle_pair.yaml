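# Size-mismatched circles: the healed boundary is a hyperbola branch
# curving away from the larger tissue (arrival-time equality d1 - R1 = d2 - R2).
world: {width: 3600, height: 3000}
default_speed: 29.5
tissues:
  - id: 1
    shape: {kind: circle, center: [750, 1500], radius: 500}
  - id: 2
    shape: {kind: circle, center: [2750, 1500], radius: 250}
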