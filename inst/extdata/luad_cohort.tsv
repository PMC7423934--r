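sample_id	group	age	sex	tumour_size_mm
AIS_T53	AIS	53	F	11
AIS_T54	AIS	74	M	29
AIS_T56	AIS	69	F	16
AIS_T58	AIS	78	M	28
AIS_T59	AIS	68	F	13
MIA_T73	MIA	58	M	20
MIA_T74	MIA	67	F	19
MIA_T75	MIA	77	F	20
MIA_T79	MIA	61	M	10
MIA_T80	MIA	63	F	12
LPA_T85	LPA	68	M	30
LPA_T87	LPA	73	F	28
LPA_T88	LPA	59	M	30
LPA_T89	LPA	67	F	20
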