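gene_id	symbol	chrom	start	end	strand	biotype	is_tf
ENSG00000170836	PPM1D	chr17	58677544	58743585	+	protein_coding	FALSE
ENSG00000141376	BCAS3	chr17	58755184	59470199	+	protein_coding	FALSE
ENSG00000121068	TBX2	chr17	59477257	59486827	+	protein_coding	TRUE
ENSG00000267128	C17orf82	chr17	59492197	59495825	+	protein_coding	FALSE
ENSG00000121075	TBX4	chr17	59533806	59567724	+	protein_coding	TRUE
ENSG00000253506	NACA2	chr17	59668129	59670269	-	protein_coding	FALSE
ENSG00000267265	TBX2-AS1	chr17	59469336	59477132	-	antisense	FALSE
ENSG00000062725	APPBP2	chr17	58522606	58600870	-	protein_coding	FALSE
ENSG00000154229	PRKCA	chr17	64298926	64806862	+	protein_coding	FALSE
ENSG00000108474	PITPNC1	chr17	65373650	65784278	-	protein_coding	FALSE
ENSG00000265666	MIR4737	chr17	59737300	59737380	+	miRNA	FALSE
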