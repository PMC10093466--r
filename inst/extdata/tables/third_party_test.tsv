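disease	total_cases	test_cases	true_cases
Acute tonsillitis	388	10	10
Acute pharyngitis	129	10	10
Acute epiglottitis	233	10	10
Acute laryngitis	204	10	10
Pharyngeal burn	0	0	0
Glossopharyngeal neuralgia	6	4	4
Peritonsillar abscess	26	10	10
Pharyngeal foreign body	11	10	10
Chronic tonsillitis	831	10	10
Cancer of the larynx	55	10	10
Chronic laryngitis	14	9	9
Chronic pharyngitis	255	10	10
Throat ulcers	45	9	9
Tonsil carcinoma	4	4	4
Styloid process syndrome	2	2	2
Infectious mononucleosis	53	10	9
Closed laryngeal trauma	8	8	8
Carcinoma of hypopharynx	15	10	10
Peritonsillitis	120	10	9
Laryngeal tuberculosis	14	10	10
Tonsil lymphoma	1	1	1
Laryngopharyngeal reflux	6	5	5
Laryngeal syphilis	0	0	0
Pharyngeal syphilis	0	0	0
Pharyngeal tuberculosis	2	2	2
Upper respiratory tract infection	157	10	10
Coronary heart disease	13	9	9
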