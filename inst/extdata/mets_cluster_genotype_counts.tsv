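snp	stratum	AA	Aa	aa
rs174537	MetS1	52	38	4
rs174537	MetS2	18	26	12
rs174570	MetS1	76	18	0
rs174570	MetS2	34	19	3
rs174575	MetS1	62	30	2
rs174575	MetS2	28	24	4
rs174602	MetS1	70	23	1
rs174602	MetS2	32	20	4
rs174589	MetS1	67	26	1
rs174589	MetS2	32	20	4
rs968567	MetS1	73	21	0
rs968567	MetS2	38	16	2
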