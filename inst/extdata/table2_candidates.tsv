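probe_id	p_fdr	gene
cg18796523	8.46e-04	ALG11;ATP7B
cg04087237	4.41e-02	CACNB4
chr16:50203861	9.91e-03	
cg13303475	1.10e-02	NT5DC3
cg01918706	4.37e-02	UBE2T
cg01657694	3.09e-02	KLHL22
cg13694867	2.54e-02	SIM2
cg05168033	1.24e-03	EFEMP1
cg26952925	1.16e-02	ADCY9
cg13562542	5.93e-03	GPR27;EIF4E3
cg17364044	3.10e-02	PELI1
cg26447413	2.02e-02	GAS1
cg11265160	1.48e-02	TMEM132C
cg21849932	1.87e-02	LIME1
cg04364540	4.27e-03	FAM160B1
cg14099514	1.02e-02	PLCXD3
cg19176559	3.46e-03	
cg19041132	6.22e-07	SPHK1
cg12053442	2.85e-02	
cg01558909	1.85e-05	HBM
cg14993491	4.54e-03	PCSK9
cg13408519	3.24e-06	
cg12604181	1.04e-09	CTSH
cg18404925	1.50e-07	RAC1
cg13978347	1.08e-04	ASTN2
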