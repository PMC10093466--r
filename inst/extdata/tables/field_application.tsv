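disease	diagnosed_cases	agreed_diagnoses
Pharyngeal foreign body	48	48
Throat ulcers	55	55
Carcinoma of hypopharynx	3	3
Glossopharyngeal neuralgia	18	18
Upper respiratory tract infection	2625	2625
Chronic pharyngitis	564	564
Chronic laryngitis	152	152
Chronic tonsillitis	65	65
Acute pharyngitis	1188	1188
Acute epiglottitis	809	809
Chronic laryngitis (second clinic group)	907	906
Acute tonsillitis	425	425
Coronary heart disease	325	325
Laryngopharyngeal reflux	29	29
Peritonsillitis	17	17
Peritonsillar abscess	6	6
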