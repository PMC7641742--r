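name: PIM1-Form1
sequence: GCGGGAGGGCGCGCCAGCGGGGTCGGG
tetrads:
- members:
  - 3
  - 25
  - 22
  - 7
  kind: G
  direction: anticlockwise
  slipped: no
- members:
  - 4
  - 8
  - 21
  - 26
  kind: G
  direction: clockwise
  slipped: no
- members:
  - 5
  - 9
  - 20
  - 27
  kind: G
  direction: clockwise
  slipped: no
pairs:
- g: 19
  c: 10
  role: stem
- g: 11
  c: 18
  role: stem
- g: 17
  c: 12
  role: stem
syn:
- 1
- 3
- 7
- 20
- 21
- 25
loops:
- kind: propeller
  from: 6
  to: 6
- kind: lateral
  from: 23
  to: 24
- kind: stem-loop
  from: 13
  to: 16
grooves:
- wide
- medium
- medium
- narrow
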