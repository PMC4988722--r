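A	1111001
B	1111111
C	0000110
D	0000000
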