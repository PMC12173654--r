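contig	pos	ref	alt	consequence	region_class
chr12	5976222	C	A	missense	exonic
chr12	6128342	G	A	missense	exonic
chr12	6094511	T	C	synonymous	exonic
chr12	6087520	T	G	sv_del	intronic
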