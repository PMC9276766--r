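# Hexagonal lattice of seven tissues that heals into a honeycomb tessellation
world: {width: 4000, height: 3600}
default_speed: 29.5
tissues:
  - id: 1
    shape:
      kind: polygon
      vertices:
        - [2430, 1800]
        - [2215, 2172.4]
        - [1785, 2172.4]
        - [1570, 1800]
        - [1785, 1427.6]
        - [2215, 1427.6]
  - id: 2
    shape:
      kind: polygon
      vertices:
        - [3296, 2300]
        - [3081, 2672.4]
        - [2651, 2672.4]
        - [2436, 2300]
        - [2651, 1927.6]
        - [3081, 1927.6]
  - id: 3
    shape:
      kind: polygon
      vertices:
        - [2430, 2800]
        - [2215, 3172.4]
        - [1785, 3172.4]
        - [1570, 2800]
        - [1785, 2427.6]
        - [2215, 2427.6]
  - id: 4
    shape:
      kind: polygon
      vertices:
        - [1564, 2300]
        - [1349, 2672.4]
        - [919, 2672.4]
        - [704, 2300]
        - [919, 1927.6]
        - [1349, 1927.6]
  - id: 5
    shape:
      kind: polygon
      vertices:
        - [1564, 1300]
        - [1349, 1672.4]
        - [919, 1672.4]
        - [704, 1300]
        - [919, 927.6]
        - [1349, 927.6]
  - id: 6
    shape:
      kind: polygon
      vertices:
        - [2430, 800]
        - [2215, 1172.4]
        - [1785, 1172.4]
        - [1570, 800]
        - [1785, 427.6]
        - [2215, 427.6]
  - id: 7
    shape:
      kind: polygon
      vertices:
        - [3296, 1300]
        - [3081, 1672.4]
        - [2651, 1672.4]
        - [2436, 1300]
        - [2651, 927.6]
        - [3081, 927.6]
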