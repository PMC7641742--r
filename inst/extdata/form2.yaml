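name: PIM1-Form2
sequence: GGGAGGGCGCGCCAGCGGGGTCGGGC
tetrads:
- members:
  - 2
  - 7
  - 18
  - 25
  kind: G
  direction: unspecified
  slipped: no
- members:
  - 3
  - 24
  - 19
  - 6
  kind: G
  direction: unspecified
  slipped: no
- members:
  - 1
  - 26
  - 17
  - 8
  kind: GCGC
  direction: unspecified
  slipped: yes
pairs:
- g: 1
  c: 26
  role: junction
- g: 17
  c: 8
  role: junction
- g: 9
  c: 16
  role: stem
- g: 15
  c: 10
  role: stem
syn:
- 2
- 6
- 18
- 24
loops:
- kind: lateral
  from: 4
  to: 5
- kind: lateral
  from: 20
  to: 23
- kind: stem-loop
  from: 11
  to: 14
grooves:
- wide
- narrow
- wide
- narrow
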