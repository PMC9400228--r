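dysregulated	arraystar_id	circbase_id	p_value	fold_change	host_gene	chrom	length_bp	start	end
Down	hsa_circRNA_001819	hsa_circ_0000658	2.829E-07	0.362	MCTP2	chr15	1502	94847149	94848651
Down	hsa_circRNA_104898	hsa_circ_0088249	5.702E-06	0.381	PAPPA	chr9	994	119106821	119130033
Down	hsa_circRNA_001484	hsa_circ_0000701	8.072E-06	0.465	CHD9	chr16	3095	53188358	53191453
Down	hsa_circRNA_000094	hsa_circ_0000247	9.871E-05	0.025	MCU	chr10	792	74474868	74475660
Down	hsa_circRNA_101122	hsa_circ_0027842	6.493E-05	0.283	ANKS1B	chr12	535	100200181	100219167
Down	hsa_circRNA_008421	hsa_circ_0008421	9.522E-05	0.374	FBN1	chr15	374	48888479	48905289
Down	hsa_circRNA_000403	hsa_circ_0000403	2.563E-05	0.433	ZNF385A	chr12	80	54764057	54764137
Down	hsa_circRNA_092561	hsa_circ_0001612	2.605E-05	0.636	SENP6	chr6	498	76331247	76357517
Down	hsa_circRNA_022382	hsa_circ_0022382	9.482E-04	0.493	FADS2	chr11	411	61605249	61608197
Down	hsa_circRNA_008786	hsa_circ_0008786	8.307E-04	0.485	POLE2	chr14	424	50120707	50122529
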