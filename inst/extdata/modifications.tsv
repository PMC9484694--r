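# Reference modification registry (example fixture): dehydration of Ser/Thr
name	delta_average	delta_monoisotopic	count	targets
dehydration	-18.0153	-18.01056	3	S,T
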