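# Approximate transmembrane/loop intervals on the 348-aa reference numbering.
# label collapses intervals to the broad class (TM, CL cytoplasmic, EL extracellular;
# N-term is extracellular, C-term cytoplasmic).
name	label	start	end
N-term	EL	1	34
TM1	TM	35	64
CL1	CL	65	73
TM2	TM	74	100
EL1	EL	101	109
TM3	TM	110	136
CL2	CL	137	152
TM4	TM	153	176
EL2	EL	177	198
TM5	TM	199	230
CL3	CL	231	252
TM6	TM	253	276
EL3	EL	277	284
TM7	TM	285	309
C-term	CL	310	348
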