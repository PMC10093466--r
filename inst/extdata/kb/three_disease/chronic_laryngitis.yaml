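name: chronic_laryngitis
sub: yes
variables:
- id: B11
  kind: B
  states: 2
  label: Chronic laryngitis
  prior:
  - 0.96
  - 0.04
- id: BX11
  kind: BX
  states: 2
  label: Chronic laryngitis incidence given risk factors
- id: SG11
  kind: SG
  states: 2
  label: Chronic laryngitis risk gate
- id: X5
  kind: X
  states: 2
  label: Subacute stage
- id: X7
  kind: X
  states: 5
  label: Age group
- id: X21
  kind: X
  states: 2
  label: Hoarseness
- id: X22
  kind: X
  states: 2
  label: Cough
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
- id: X52
  kind: X
  states: 2
  label: Male sex
- id: X85
  kind: X
  states: 2
  label: Sore throat
- id: X153
  kind: X
  states: 2
  label: Vocal cord edema
links:
- child: X153
  parent: BX11
  r: 1.0
  strength:
  - - 0.0
    - 0.3
- child: X21
  parent: BX11
  r: 1.0
  strength:
  - - 0.0
    - 0.7
- child: X22
  parent: BX11
  r: 1.0
  strength:
  - - 0.0
    - 0.35
- child: X44
  parent: BX11
  r: 1.0
  strength:
  - - 0.0
    - 0.3
- child: X45
  parent: BX11
  r: 1.0
  strength:
  - - 0.0
    - 0.3
- child: X51
  parent: BX11
  r: 1.0
  strength:
  - - 0.0
    - 0.4
- child: X85
  parent: BX11
  r: 1.0
  strength:
  - - 0.0
    - 0.5
gates:
- id: SG11
  remnant: 0
  rows:
  - state: 2
    expr: X5=1 & X52=1
  - state: 1
    expr: X5=1 | X52=1 | X7=4
sa:
- disease: B11
  bx: BX11
  gate: SG11
  factors:
  - 1.0
  - 3.0
  - 5.0
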