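# toy taxonomy T0: child <TAB> parent [<TAB> relation-label]
C	A
D	A
A	R
B	R
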