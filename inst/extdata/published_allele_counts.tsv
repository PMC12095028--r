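GENE	CHROM	POS	REF	ALT	MODE	CASE_AC	CASE_AN	DB_NAME	DB_AC	DB_AN	PARENT_AC	PARENT_AN
DNAH2	chr17	7726926	C	T	de_novo	1	104	gnomad_eas	1	19954	0	208
DNAH2	chr17	7726926	C	T	de_novo	1	104	han			0	208
FLNA	chrX	153578474	G	A	x_linked_recessive	1	52	gnomad_eas			1	156
FLNA	chrX	153578474	G	A	x_linked_recessive	1	52	han			1	156
DNAH2	chr17	7702004	C	T	compound_het	1	104	gnomad_eas	13	18392	1	208
DNAH2	chr17	7702004	C	T	compound_het	1	104	han	33	41916	1	208
DNAH2	chr17	7722374	C	T	compound_het	1	104	gnomad_eas	4	19634	1	208
DNAH2	chr17	7722374	C	T	compound_het	1	104	han	5	28398	1	208
DNAH11	chr7	21630934	G	A	chd_lof	1	104	gnomad_eas			1	208
DNAH11	chr7	21630934	G	A	chd_lof	1	104	han			1	208
DNAH11	chr7	21912981	GAT	G	chd_lof	1	104	gnomad_eas			1	208
DNAH11	chr7	21912981	GAT	G	chd_lof	1	104	han			1	208
DNAH11	chr7	21847548	GACTC	G	chd_lof	1	104	gnomad_eas			1	208
DNAH11	chr7	21847548	GACTC	G	chd_lof	1	104	han			1	208
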