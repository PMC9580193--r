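code	descriptor	parent	language
B01	Vacuna antigripal		es
B02	Vacuna hepatitis A inactivada		es
B03	Vacuna tos ferina acelular		es
B04	Vacuna contra el virus del papiloma humano		es
B05	Vacuna tetanos toxoide		es
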