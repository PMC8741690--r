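snp_id	chrom	pos	risk_allele	other_allele	weight
rs_hla_syn	6	32600000	A	G	0.800
rs_syn01	1	11400210	C	T	0.180
rs_syn02	1	64107890	G	A	0.192
rs_syn03	2	25301450	T	C	0.204
rs_syn04	2	100190340	A	C	0.216
rs_syn05	2	204738300	G	T	0.229
rs_syn06	3	46210055	C	G	0.241
rs_syn07	4	26085920	A	T	0.253
rs_syn08	4	123210480	T	G	0.265
rs_syn09	5	35880770	C	A	0.277
rs_syn10	6	90980400	G	C	0.289
rs_syn11	7	26890110	A	G	0.301
rs_syn12	7	50465830	T	A	0.314
rs_syn13	9	4290085	C	T	0.326
rs_syn14	10	6094800	G	A	0.338
rs_syn15	10	90035910	A	C	0.350
rs_syn16	11	2182220	T	C	0.362
rs_syn17	11	64107350	C	G	0.374
rs_syn18	12	56435500	G	T	0.386
rs_syn19	12	111884600	A	T	0.399
rs_syn20	13	42873390	T	G	0.411
rs_syn21	14	69263600	C	A	0.423
rs_syn22	14	98488420	G	C	0.435
rs_syn23	15	38847020	A	G	0.447
rs_syn24	16	11194770	T	A	0.459
rs_syn25	16	75252330	C	T	0.471
rs_syn26	17	38053200	G	A	0.484
rs_syn27	18	12809340	A	C	0.496
rs_syn28	19	10463120	T	C	0.508
rs_syn29	22	30531090	C	G	0.520
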