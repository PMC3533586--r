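# synthetic rating file: concept1 <TAB> concept2 <TAB> mean human rating
C	D	3.6
C	B	1.2
A	B	1.8
A	D	2.9
B	D	1.1
A	C	3.1
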