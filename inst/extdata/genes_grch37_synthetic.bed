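# genome=GRCh37
# synthetic fixture: approximate GRCh37 gene spans of the chr12p13.31 tandem-repeat region
chr12	7941991	7948657	NANOG
chr12	7965107	8028513	SLC2A14
chr12	8044528	8051812	NANOGP1
chr12	8071824	8088871	SLC2A3
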