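code	descriptor	parent	language
T01	Influenza virus vaccine		en
T02	Hepatitis A, inactivated		en
T03	Acellular pertussis vaccine		en
T04	Human papillomavirus vaccine		en
T05	Tetanus toxoid vaccine		en
T06	Tuberculosis vaccine		en
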