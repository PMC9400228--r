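dysregulated	arraystar_id	circbase_id	p_value	fold_change	host_gene	chrom	length_bp	start	end
Up	hsa_circRNA_026358	hsa_circ_0026358	6.559E-06	2.037	KRT7	chr12	534	52628938	52635420
Up	hsa_circRNA_025042	hsa_circ_0025042	4.266E-05	1.688	FOXM1	chr12	549	2983142	2983691
Up	hsa_circRNA_101929	hsa_circ_0004931	6.379E-05	1.642	NXN	chr17	460	722678	729318
Up	hsa_circRNA_000756	hsa_circ_0000756	8.923E-05	1.644	ATAD5	chr17	1366	29170930	29196664
Up	hsa_circRNA_007923	hsa_circ_0007923	7.750E-05	1.632	RRM1	chr11	631	4123222	4133292
Up	hsa_circRNA_101081	hsa_circ_0000408	2.511E-05	1.503	TIMELESS	chr12	378	56824664	56826308
Up	hsa_circRNA_104564	hsa_circ_0083444	8.186E-05	1.549	MTUS1	chr8	2441	17601112	17613470
Up	hsa_circRNA_103069	hsa_circ_0060516	2.781E-04	1.560	PABPC1L	chr20	235	43547546	43547918
Up	hsa_circRNA_407080	NA	4.701E-03	1.629	CHD7	chr8	NA	61707544	61714152
Up	hsa_circRNA_403287	NA	9.186E-05	1.544	LPCAT1	chr5	NA	1488505	1501718
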