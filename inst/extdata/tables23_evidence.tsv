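# Curated combined-evidence table for the UVS and LWS paralog screens.
# One row per substitution record; pairs are ordered paralog residue pairs 'A>B',
# semicolon-separated. expected_labels is the union of classifier label kinds over
# the row's pairs. printed_significance is the source wording verbatim (direction
# conventions in the source are inconsistent; agreement is judged modulo direction,
# with classifier-found labels beyond the print tolerated). exception = 1 flags the
# two rows (A-V, C-I) where the printed labels conflict in substance with the
# heavy-atom-count size rule. '.' marks an empty field.
gene_class	site	region	in_cbp	ps_lineage	branch	pairs	printed_significance	expected_labels	exception	agrees_with_print	lit_ps	lit_shift	notes
UVS	12	EL	0	Acmaeodera diffusa UVS2	UV-F	V>P	imposed backbone rigidity	gain_backbone_rigidity	0	1	Heliconius_UV_A37E[CR28]	.	.
UVS	105	EL	0	Buprestidae UVS1	UV-C	T>T;T>L	gain of polarity (T-L)	loss_of_polarity	0	1	Heliconius_UV_T121I[CR28]	.	printed direction reversed; fixed paralog1->paralog2 convention yields loss
UVS	105	EL	0	Acmaeodera diffusa UVS2	UV-F	A>L	increase in size	increase_in_size	0	1	.	.	.
UVS	107	EL	0	Buprestidae UVS2	UV-D	H>F;H>M;H>Y	loss of positive charge (to polar or neutral), increase in size (H-Y)	loss_of_positive_charge;increase_in_size;decrease_in_size	0	1	Heliconius_UV_A123S/T[CR28]	.	H>M size decrease beyond print
UVS	118	TM3	1	.	.	T>T;S>T	most likely insignificant	most_likely_insignificant	0	1	Photinus_UVS_S133[CR43]	Pieris_rapae_SWS_S116A_13nm_hypsochromic[CR11]	.
UVS	125	TM3	0	Acmaeodera diffusa UVS2	UV-F	G>S	gain of polarity, increase in size	gain_of_polarity;increase_in_size	0	1	.	Vertebrate_Rh1_125_-5_to_+8nm[CR75]	.
UVS	137	CL	0	Buprestidae UVS2	UV-D	T>H	gain of positive charge (from polar), increase in size	gain_of_positive_charge;increase_in_size	0	1	.	Mammal_rhodopsin_V137M_retinitis_pigmentosa[CR76]	.
UVS	172	TM4	0	Acmaeodera diffusa UVS2	UV-F	F>Y	gain of polarity	gain_of_polarity	0	1	.	Lepidoptera_LWS_L145M/F/I_blue_shifts[CR78]	.
UVS	186	EL	1	Buprestidae UVS2	UV-D	A>Q	gain of polarity, increase in size	gain_of_polarity;increase_in_size	0	1	Heliconius_UVS_S202A[CR28]	.	.
UVS	188	EL	1	Acmaeodera diffusa UVS2	UV-F	S>G	loss of polarity, decrease in size	loss_of_polarity;decrease_in_size	0	1	Heliconius_UVS_T204S[CR28]	.	.
UVS	207	TM5	1	Buprestidae UVS2	UV-D	I>L	most likely insignificant	most_likely_insignificant	0	1	.	Vertebrate_SWS_L207M/I_6nm[CR82;CR83]	.
UVS	242^a	CL	0	Buprestidae UVS2	UV-D	A>Q	gain of polarity, increase in size	gain_of_polarity;increase_in_size	0	1	Photinus_UVS_A268[CR43]	.	insertion site between reference 242 and 243
UVS	242^a	CL	0	.	.	T>Q;S>Q	change in polarity, increase in size	increase_in_size	0	1	.	.	printed change-in-polarity maps to no label kind (both residues polar)
UVS	261	TM6	1	.	.	F>F;Y>F	loss of polarity (Y-F)	loss_of_polarity	0	1	.	Human_Y277F_red_green_variation[CR81];Vertebrate_SWS_T261F_5nm_blue[CR82]	.
UVS	272	TM6	0	Acmaeodera diffusa UVS2	UV-F	S>C	gain of potential for disulfide bonding	gain_disulfide_potential	0	1	Photinus_UVS_S299[CR43]	.	.
UVS	293	TM7	0	Acmaeodera diffusa UVS2	UV-F	C>L	loss of polarity and potential for disulfide bonding	loss_of_polarity;loss_disulfide_potential;increase_in_size	0	1	Heliconius_UVS_V321I[CR28]	Human_Y309F_red_green_variation[CR81]	size change beyond print (heavy-atom diff 2)
UVS	294	TM7	0	Buprestidae UVS1	UV-C	F>T;F>A	loss of polarity (F-T), increase in size	gain_of_polarity;decrease_in_size	0	1	Photinus_UVS_T321[CR43]	.	printed direction reversed
UVS	294	TM7	0	Acmaeodera diffusa UVS2	UV-F	C>F	increase in size, loss of polarity and potential for disulfide bonding	increase_in_size;loss_of_polarity;loss_disulfide_potential	0	1	.	.	.
LWS	44	TM1	0	.	.	I>I;I>M	most likely insignificant (I-M)	most_likely_insignificant	0	1	Limenitis_LWS_I17M_PS_blue[CR21;CR78];Lepidoptera_I44M[CR77]	Mammal_rhodopsin_M44T_3nm_blue[CR76]	.
LWS	46	TM1	0	Buprestidae LWS1	LW-E	T>V	gain of polarity	loss_of_polarity	0	1	.	Vertebrate_SWS_F46A/L[CR79;CR83]	printed direction reversed
LWS	46	TM1	0	.	.	I>V	most likely insignificant	most_likely_insignificant	0	1	.	.	.
LWS	46	TM1	0	.	.	C>I	gain of polarity and potential for disulfide bonding	loss_of_polarity;loss_disulfide_potential;increase_in_size	1	0	.	.	documented exception: printed labels omit the heavy-atom size change for C-I
LWS	91	TM2	0	.	.	A>V	most likely insignificant (A-V)	increase_in_size	1	0	Limenitis_LWS_A64S_PS_blue[CR21;CR78]	Vertebrate_SWS_P91S_10nm_blue[CR82]	documented exception: printed insignificant but heavy-atom diff 2
LWS	91	TM2	0	.	.	A>S	gain of polarity (A-S)	gain_of_polarity	0	1	.	.	.
LWS	93	TM2	0	Acmaeodera diffusa LWS2	LW-F	P>E	gain of backbone flexibility, increase in size, gain of negative charge (from neutral)	gain_backbone_flexibility;increase_in_size;gain_of_negative_charge	0	1	.	Vertebrate_SWS_T93L/V[CR74;CR83]	.
LWS	122	TM3	1	.	.	T>C;C>C	gain of potential for disulfide bonding (T-C)	gain_disulfide_potential	0	1	.	Bovine_E122Q_17nm_blue[CR12];Vertebrate_SWS_I122M_6nm_blue[CR82]	.
LWS	123	TM3	0	Coleoptera LWS (some) + Agrilus planipennis LWS3 (male)	LW-H	V>I;T>I	loss of polarity (T-I) or most likely insignificant (V-I)	loss_of_polarity;most_likely_insignificant	0	1	.	Lepidoptera_LW_97[CR8;CR20]	.
LWS	123	TM3	0	Buprestidae LWS1	LW-E	V>T;A>T	loss of polarity	gain_of_polarity;increase_in_size	0	1	.	.	printed direction reversed; A>T size beyond print
LWS	156	TM4	0	Coleoptera LWS (some) + Agrilus planipennis LWS3 (male)	LW-H	W>R;W>Q;R>Q	gain of positive charge from neutral (W-R), gain of polarity (W-Q), loss of positive charge (to polar) and decrease in size (R-Q)	gain_of_positive_charge;loss_of_positive_charge;gain_of_polarity;decrease_in_size	0	1	Heliconius_UVS_M171L[CR28]	.	W>R and W>Q size decreases beyond print
LWS	156	TM4	0	Acmaeodera diffusa LWS1	LW-G	W>R	loss of positive charge (to neutral)	gain_of_positive_charge;decrease_in_size	0	1	.	.	printed direction reversed; size beyond print
LWS	164	TM4	0	.	.	S>S;S>T;T>S;T>T;S>C;T>C;S>A;T>A	most likely insignificant (S/T-S/T); gain of potential for disulfide bonding (S/T-C); loss of polarity (S/T-A)	most_likely_insignificant;gain_disulfide_potential;loss_of_polarity;decrease_in_size	0	1	Limenitis_LWS_S137A_PS_blue[CR21];Lepidoptera_S138A[CR77]	Human_S180A_red_green_5nm[CR73;CR81]	T>A size beyond print
LWS	170	TM4	0	Coleoptera LWS (some) + Agrilus planipennis LWS3 (male)	LW-H	A>A;A>L	increase in size (A-L)	increase_in_size	0	1	Heliconius_UVS_M185L[CR28]	.	.
LWS	197	EL	0	Coleoptera LWS (some) + Agrilus planipennis LWS3 (male)	LW-H	D>D;D>E	most likely insignificant (D-E)	most_likely_insignificant	0	1	.	Lepidoptera_LWS_170_blue[CR78];Vertebrate_LWS_197[CR80]	.
LWS	211	TM5	1	Buprestidae LWS1	LW-E	C>V	gain of polarity and disulfide bond potential	loss_of_polarity;loss_disulfide_potential	0	1	Heliconius_UVS_S125T/A[CR28]	Bovine_Rh1_H211C_5nm[CR12];Vertebrate_SWS_S211C_2nm_blue[CR82]	printed direction reversed
LWS	242^a	CL	0	Acmaeodera diffusa LWS1	LW-G	A>A	no substitution		0	1	Photinus_UVS_A268[CR43]	.	invariant in Acmaeodera diffusa; varies in other buprestids
LWS	269	TM6	1	.	.	L>L;A>L;M>L	increase in size (A-L); most likely insignificant (M-L)	increase_in_size;most_likely_insignificant	0	1	.	Bovine_LWS_A269T_14nm_red[CR9];Human_T269A_red_green_15nm[CR73;CR81]	.
LWS	274	TM6	0	Buprestidae LWS1 + Acmaeodera diffusa LWS2	LW-C	T>T;V>T;L>T;A>T	loss of polarity (V/L/A-T)	gain_of_polarity;increase_in_size	0	1	.	Lepidoptera_LWS_259[CR20]	printed direction reversed; A>T size beyond print
LWS	281	EL	0	Coleoptera LWS (some) + Agrilus planipennis LWS3 (male)	LW-H	A>A;A>K	gain of positive charge (from neutral) and increase in size (A-K)	gain_of_positive_charge;increase_in_size	0	1	Photinus_LWS_T309[CR43]	.	.
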