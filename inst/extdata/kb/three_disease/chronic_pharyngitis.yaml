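name: chronic_pharyngitis
sub: yes
variables:
- id: B12
  kind: B
  states: 2
  label: Chronic pharyngitis
  prior:
  - 0.91
  - 0.09
- id: X21
  kind: X
  states: 2
  label: Hoarseness
- id: X23
  kind: X
  states: 2
  label: Expectoration
- id: X44
  kind: X
  states: 2
  label: Throat itching
- id: X45
  kind: X
  states: 2
  label: Foreign body sensation in throat
- id: X51
  kind: X
  states: 2
  label: Dry throat
- id: X85
  kind: X
  states: 2
  label: Sore throat
- id: X150
  kind: X
  states: 2
  label: Throat clearing
links:
- child: X150
  parent: B12
  r: 1.0
  strength:
  - - 0.0
    - 0.4
- child: X21
  parent: B12
  r: 1.0
  strength:
  - - 0.0
    - 0.15
- child: X23
  parent: B12
  r: 1.0
  strength:
  - - 0.0
    - 0.3
- child: X44
  parent: B12
  r: 1.0
  strength:
  - - 0.0
    - 0.5
- child: X45
  parent: B12
  r: 1.0
  strength:
  - - 0.0
    - 0.6
- child: X51
  parent: B12
  r: 1.0
  strength:
  - - 0.0
    - 0.5
- child: X85
  parent: B12
  r: 1.0
  strength:
  - - 0.0
    - 0.45
gates: []
sa: []
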