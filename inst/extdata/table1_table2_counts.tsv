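# deletion-carrier by case/control counts per population stratum
# a = case carriers, b = case non-carriers, c = control carriers, d = control non-carriers
stratum	a	b	c	d
sweden	28	2375	33	1236
uk	9	1837	67	7288
us	11	1956	9	987
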