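# raw corpus counts for the toy taxonomy (concept <TAB> count)
C	2
D	3
B	5
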