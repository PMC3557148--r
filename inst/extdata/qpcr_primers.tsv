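gene	role	forward_primer	reverse_primer	product_bp
dpep1	test	GACAACTGGCTGGTGGACA	ACCACACGCTGCCCAAA	74
cldn1	test	GCTGTCATTGGGGGTGCGAT	GGCAACTAAAATAGCCAGACCTGC	54
ubc	reference	GGTCGCAGTTCTTGTTTGTGG	CACGAAGATCTGCATTGTCAAG	59
b2m	reference	TGCTGTCTCCATGTTTGATGTATCT	TCTCTGCTCCCCACCTCTAAGT	86
atp5e	reference	CTGGACTCAGCTACATCCGA	GCATCTCTCACTGCTTTTGCAC	55
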