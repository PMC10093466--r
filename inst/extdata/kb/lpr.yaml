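name: lpr
sub: yes
variables:
- id: B23
  kind: B
  states: 2
  label: Laryngopharyngeal reflux
  prior:
  - 0.97
  - 0.03
- id: BX23
  kind: BX
  states: 2
  label: LPR incidence given risk factors
- id: C23
  kind: C
  states: 2
  label: LPR manifestation group
- id: SG23
  kind: SG
  states: 2
  label: LPR risk-factor gate
- id: SX160
  kind: SX
  states: 2
  label: Proton pump inhibitors are effective
- id: X21
  kind: X
  states: 2
  label: Hoarseness
- id: X45
  kind: X
  states: 2
  label: Foreign body sensation in throat
- id: X74
  kind: X
  states: 2
  label: History of reflux esophagitis
- id: X85
  kind: X
  states: 2
  label: Sore throat
- id: X150
  kind: X
  states: 2
  label: Throat clearing
- id: X153
  kind: X
  states: 2
  label: Vocal cord edema
- id: X158
  kind: X
  states: 2
  label: Pharyngeal pH monitoring positive
links:
- child: SX160
  parent: BX23
  r: 1.0
  strength:
  - - 0.0
    - 0.9
- child: X150
  parent: BX23
  r: 1.0
  strength:
  - - 0.0
    - 0.55
- child: X153
  parent: BX23
  r: 1.0
  strength:
  - - 0.0
    - 0.45
- child: X158
  parent: BX23
  r: 1.0
  strength:
  - - 0.0
    - 0.7
- child: X21
  parent: BX23
  r: 1.0
  strength:
  - - 0.0
    - 0.5
- child: X45
  parent: BX23
  r: 1.0
  strength:
  - - 0.0
    - 0.4
- child: X85
  parent: BX23
  r: 1.0
  strength:
  - - 0.0
    - 0.4
gates:
- id: SG23
  remnant: 0
  rows:
  - state: 1
    expr: X74=1
sa:
- disease: B23
  bx: BX23
  gate: SG23
  factors:
  - 1.0
  - 10.0
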