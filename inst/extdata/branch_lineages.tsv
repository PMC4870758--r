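# Branch-site positive-selection foreground branches and the lineages they test.
# paralog_wide = 1 marks branches spanning a whole buprestid paralog clade.
branch	gene_class	paralog_wide	lineage
UV-C	UVS	1	Buprestidae UVS1
UV-D	UVS	1	Buprestidae UVS2
UV-F	UVS	0	Acmaeodera diffusa UVS2
LW-C	LWS	1	Buprestidae LWS1 + Acmaeodera diffusa LWS2
LW-E	LWS	1	Buprestidae LWS1
LW-F	LWS	0	Acmaeodera diffusa LWS2
LW-G	LWS	0	Acmaeodera diffusa LWS1
LW-H	LWS	0	Coleoptera LWS (some) + Agrilus planipennis LWS3 (male)
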