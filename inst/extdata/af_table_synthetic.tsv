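contig	pos	ref	alt	af
chr12	5976222	C	A	0.0049998
chr12	6128342	G	A	0.1520000
chr12	6094511	T	C	0.0003100
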