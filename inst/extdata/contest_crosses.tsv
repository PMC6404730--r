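maternal_strain	balb_dominant	cba_dominant
PT	21	10
DD	16	4
C57BL/6J	13	7
YT	16	5
A/He	13	10
TOTAL	79	36
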