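source_code	target_code
B01	T01
B02	T02
B03	T03
B04	T04
B05	T05
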