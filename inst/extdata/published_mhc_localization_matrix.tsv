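row_label	pct_Cytoplasm	pct_Cytoplasmic_membrane	pct_Extracellular	pct_Periplasm	pct_Unknown	total
All Geobacter spp.	5	4	21	22	48	384
All others	10	22	5	25	38	302
S0_RifleGW_Geobacter_53_40	1	3	22	18	56	72
MHCs with 3-14 hemes	10	12	14	21	43	582
MHCs with 15-27 hemes	13	0	20	26	41	66
MHCs with 30-53 hemes	0	0	31	0	69	38
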