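# synthetic 21-amplicon tiling scheme (example only; not a published primer set)
id	contig	start	end	anchor_seq	anchor_end_window
PCR01	chr12	0	13500		2000
PCR02	chr12	8500	22000		2000
PCR03	chr12	17000	30500		2000
PCR04	chr12	25500	39000		2000
PCR05	chr12	34000	47500		2000
PCR06	chr12	42500	56000		2000
PCR07	chr12	51000	64500		2000
PCR08	chr12	59500	73000		2000
PCR09	chr12	68000	81500		2000
PCR10	chr12	76500	90000		2000
PCR11	chr12	85000	98500		2000
PCR12	chr12	93500	107000		2000
PCR13	chr12	102000	115500		2000
PCR14	chr12	110500	124000		2000
PCR15	chr12	119000	132500		2000
PCR16	chr12	127500	141000		2000
PCR17	chr12	136000	149500		2000
PCR18	chr12	144500	158000		2000
PCR19	chr12	153000	166500		2000
PCR20	chr12	161500	175000		2000
PCR21	chr12	170000	183500		2000
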