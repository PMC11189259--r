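group	organ	n_individuals	X	Y	XY	nSC
WT	testis	3	760	626	14	57
WT	spermatheca	3	371	365	5	63
AgY53B_2L	testis	6	145	89	561	14
AgY53B_2L	spermatheca	4	414	177	68	19
AgY53B_2R	testis	5	782	896	474	180
AgY53B_2R	spermatheca	5	1005	592	69	94
AgPMB1_AgY53B_2R	testis	3	327	361	254	116
AgPMB1_AgY53B_2R	spermatheca	4	467	537	252	119
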