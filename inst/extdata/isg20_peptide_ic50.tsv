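peptide_id	sequence	kinase	ic50	ci_lower	ci_upper
WT	IRARRGLPRLAVSD	WT	5.4	4.8	6.2
WT	IRARRGLPRLAVSD	R133K	220	198	253
WT	IRARRGLPRLAVSD	D319N	230	187	290
WT	IRARRGLPRLAVSD	E320K	330	270	399
I1N	NRARRGLPRLAVSD	WT	190	168	204
I1N	NRARRGLPRLAVSD	R133K	180	154	211
I1N	NRARRGLPRLAVSD	D319N	230	181	287
I1N	NRARRGLPRLAVSD	E320K	260	224	291
R4A	IRAARGLPRLAVSD	WT	250	215	285
R4A	IRAARGLPRLAVSD	R133K	380	310	470
R4A	IRAARGLPRLAVSD	D319N	320	263	395
R4A	IRAARGLPRLAVSD	E320K	300	249	368
R5A	IRARAGLPRLAVSD	WT	250	215	304
R5A	IRARAGLPRLAVSD	R133K	480	398	585
R5A	IRARAGLPRLAVSD	D319N	440	361	551
R5A	IRARAGLPRLAVSD	E320K	400	320	508
I1R_R2I	RIARRGLPRLAVSD	WT	200	185	215
I1R_R2I	RIARRGLPRLAVSD	R133K	220	193	259
I1R_R2I	RIARRGLPRLAVSD	D319N	310	268	368
I1R_R2I	RIARRGLPRLAVSD	E320K	280	243	322
G2plus	IGRARRGLPRLAVSD	WT	120	107	125
G2plus	IGRARRGLPRLAVSD	R133K	150	130	167
G2plus	IGRARRGLPRLAVSD	D319N	150	125	185
G2plus	IGRARRGLPRLAVSD	E320K	170	143	202
G7plus	IRARRGGLPRLAVSD	WT	75	71	80
G7plus	IRARRGGLPRLAVSD	R133K	170	152	198
G7plus	IRARRGGLPRLAVSD	D319N	150	122	180
G7plus	IRARRGGLPRLAVSD	E320K	210	181	242
G6Q	IRARRQLPRLAVSD	WT	41	38	43
G6Q	IRARRQLPRLAVSD	R133K	99	85	115
G6Q	IRARRQLPRLAVSD	D319N	93	77	113
G6Q	IRARRQLPRLAVSD	E320K	150	129	167
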