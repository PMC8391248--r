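snp_id	target_group	source_panels
rs10497191	AFR	Kiddlab;LACE
rs1197062	AFR	gAIMs;LACE
rs1369290	AFR	gAIMs
rs2789823	AFR	gAIMs
rs2814778	AFR	Kiddlab;gAIMs
rs310644	AFR	Kiddlab;gAIMs
rs4737753	AFR	NAME
rs11778591	EUR	gAIMs;LACE
rs12142199	EUR	gAIMs
rs12913832	EUR	Kiddlab;gAIMs
rs1426654	EUR	Kiddlab;gAIMs
rs16891982	EUR	Kiddlab;gAIMs
rs2715883	EUR	gAIMs
rs3759171	EUR	gAIMs;LACE
rs705308	EUR	PIAP
rs7084970	EUR	gAIMs
rs7531501	EUR	gAIMs
rs8072587	EUR	gAIMs
rs820371	EUR	gAIMs;LACE
rs862500	EUR	gAIMs;LACE
rs917115	EUR	Kiddlab;gAIMs
rs9522149	EUR	Kiddlab;gAIMs
rs10149275	OCE	gAIMs
rs16830500	OCE	gAIMs
rs2139931	OCE	gAIMs
rs2274636	OCE	gAIMs
rs26951	OCE	gAIMs
rs3751050	OCE	gAIMs
rs3804030	OCE	gAIMs
rs4391951	OCE	gAIMs
rs4959270	OCE	Pacifiplex
rs6054465	OCE	gAIMs
rs715605	OCE	gAIMs
rs9908046	OCE	gAIMs
rs9934011	OCE	gAIMs
rs10012227	AMR	gAIMs
rs10483251	AMR	gAIMs;LACE
rs12130799	AMR	PIAP
rs12498138	AMR	Kiddlab;gAIMs
rs12629908	AMR	PIAP
rs1452501	AMR	gAIMs;LACE
rs1557553	AMR	gAIMs;LACE
rs17130385	AMR	gAIMs;LACE
rs17359176	AMR	gAIMs;LACE
rs174570	AMR	Kiddlab;gAIMs;LACE
rs2302013	AMR	gAIMs
rs2471552	AMR	gAIMs
rs3737576	AMR	Kiddlab
rs4792928	AMR	gAIMs
rs5757362	AMR	LACE
rs8137373	AMR	gAIMs
rs870347	AMR	Kiddlab
rs10079352	EAS	gAIMs;LACE
rs1229984	EAS	Kiddlab;gAIMs
rs12594144	EAS	gAIMs
rs1371048	EAS	gAIMs
rs17822931	EAS	gAIMs
rs1834619	EAS	Kiddlab;gAIMs
rs2180052	EAS	gAIMs
rs3827760	EAS	Kiddlab;gAIMs
rs434504	EAS	gAIMs
rs459920	EAS	Kiddlab
rs4657449	EAS	gAIMs
rs4781011	EAS	PIAP
rs4918664	EAS	Kiddlab;gAIMs
rs4935501	EAS	gAIMs
rs7226659	EAS	Kiddlab
rs8104441	EAS	gAIMs
rs1040934	SAS	Shriver
rs1063677	SAS	Shriver
rs10764919	SAS	LACE
rs10962599	SAS	Eurasiaplex
rs13267318	SAS	Shriver
rs13280988	SAS	LACE
rs17625895	SAS	Eurasiaplex
rs1796048	SAS	Shriver
rs1924381	SAS	gAIMs;LACE
rs2026999	SAS	Shriver
rs2196051	SAS	Kiddlab;Eurasiaplex
rs2238151	SAS	Kiddlab
rs2269793	SAS	PIAP
rs2472304	SAS	Eurasiaplex
rs2503770	SAS	gAIMs;LACE
rs26247	SAS	Shriver
rs3844336	SAS	Shriver
rs7080350	SAS	LACE
rs7568054	SAS	LACE
rs756913	SAS	Eurasiaplex
rs1495085	EURASIA	NAME
rs1757928	EURASIA	NAME
rs2337024	EURASIA	NAME
rs6989963	EURASIA	NAME
rs6990312	EURASIA	Kiddlab
rs7148809	EURASIA	NAME
rs12203115	EURASIA	NAME
rs2227203	EURASIA	NAME
rs39897	EURASIA	Eurasiaplex
rs4308478	EURASIA	NAME
rs7570971	EURASIA	NAME
rs984038	EURASIA	NAME
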