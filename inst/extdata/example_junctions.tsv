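# junction-assay presence/absence calls for the example profiles
sample	del_junction	dup_junction
eu_del	TRUE	FALSE
eu_dup	FALSE	TRUE
yri_dup	FALSE	FALSE
normal	FALSE	FALSE
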