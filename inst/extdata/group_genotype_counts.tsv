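snp	stratum	AA	Aa	aa
rs174537	MetS	70	64	16
rs174537	CON	74	91	15
rs174537	CON1	34	31	3
rs174537	CON2	40	60	12
rs174570	MetS	110	37	3
rs174570	CON	135	44	1
rs174570	CON1	56	12	0
rs174570	CON2	79	32	1
rs174575	MetS	90	54	6
rs174575	CON	95	74	11
rs174575	CON1	41	23	4
rs174575	CON2	54	51	7
rs174602	MetS	102	43	5
rs174602	CON	122	54	4
rs174602	CON1	51	16	1
rs174602	CON2	71	38	3
rs174589	MetS	99	46	5
rs174589	CON	117	61	2
rs174589	CON1	50	18	0
rs174589	CON2	67	43	2
rs968567	MetS	111	37	2
rs968567	CON	123	54	3
rs968567	CON1	50	17	1
rs968567	CON2	73	37	2
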