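# synthetic partial-PRT profiles in the style of observed variant haplotypes:
# eu_del / eu_dup cross between B9 and B10 (the AB1 breakpoint); yri_dup between B5 and B6
sample	locus	log2_value
eu_del	P1	-1.0
eu_del	B5	-1.0
eu_del	B6	-1.0
eu_del	B8	-1.0
eu_del	B9	-1.0
eu_del	B10	1.0
eu_dup	P1	0.585
eu_dup	B5	0.585
eu_dup	B6	0.585
eu_dup	B8	0.585
eu_dup	B9	0.585
eu_dup	B10	-0.585
yri_dup	P1	0.585
yri_dup	B5	0.585
yri_dup	B6	-0.585
yri_dup	B8	-0.585
yri_dup	B9	-0.585
yri_dup	B10	-0.585
normal	P1	0.0
normal	B5	0.0
normal	B6	0.0
normal	B8	0.0
normal	B9	0.0
normal	B10	0.0
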