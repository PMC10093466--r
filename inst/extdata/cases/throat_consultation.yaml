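# A staged otolaryngology consultation for the three-disease knowledge
# base: symptoms at presentation, then the laryngoscopy finding, then the
# laboratory work-up. Each stage is diagnosed with the accumulated
# evidence.
- label: presenting symptoms
  observations:
    X7: 4     # age group: young adult
    X52: 1    # male
    X5: 1     # subacute stage
    X85: 1    # sore throat
    X21: 1    # hoarseness
    X45: 1    # foreign body sensation
    X44: 1    # throat itching
    X150: 1   # throat clearing
    X51: 0    # dry throat absent
    X22: 0    # cough absent
    X23: 0    # expectoration absent
- label: after physical examination
  observations:
    X7: 4
    X52: 1
    X5: 1
    X85: 1
    X21: 1
    X45: 1
    X44: 1
    X150: 1
    X51: 0
    X22: 0
    X23: 0
    X153: 1   # laryngoscopy: vocal cord edema
- label: after laboratory tests
  observations:
    X7: 4
    X52: 1
    X5: 1
    X85: 1
    X21: 1
    X45: 1
    X44: 1
    X150: 1
    X51: 0
    X22: 0
    X23: 0
    X153: 1
    X158: 1   # pharyngeal pH monitoring positive
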