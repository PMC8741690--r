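snp_id	case_freq	background_freq
rs_hla_syn	0.936	0.763
rs_syn01	0.044	0.010
rs_syn02	0.044	0.010
rs_syn03	0.044	0.010
rs_syn04	0.954	0.822
rs_syn05	0.044	0.010
rs_syn06	0.044	0.010
rs_syn07	0.954	0.822
rs_syn08	0.044	0.010
rs_syn09	0.044	0.010
rs_syn10	0.044	0.010
rs_syn11	0.044	0.010
rs_syn12	0.044	0.010
rs_syn13	0.954	0.822
rs_syn14	0.044	0.010
rs_syn15	0.044	0.010
rs_syn16	0.954	0.822
rs_syn17	0.044	0.010
rs_syn18	0.044	0.010
rs_syn19	0.044	0.010
rs_syn20	0.044	0.010
rs_syn21	0.044	0.010
rs_syn22	0.954	0.822
rs_syn23	0.044	0.010
rs_syn24	0.044	0.010
rs_syn25	0.954	0.822
rs_syn26	0.044	0.010
rs_syn27	0.044	0.010
rs_syn28	0.044	0.010
rs_syn29	0.044	0.010
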