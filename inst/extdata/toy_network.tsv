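D1	activation	P1
P1	inhibition	P2
P2	association	Dis1
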