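patient	clonality	gene	consequence	aa_change	relevance_printed	reason_printed
Pat1	common	CSMD1	missense	Val2977Met	high	SIFT score < 0.05
Pat1	common	KRAS	missense	Gly12Asp	high	known mutation
Pat1	common	SMAD4	missense	Ser72Thr	high	SIFT score < 0.05
Pat1	common	FAT2	missense	Arg2024Thr	unknown	.
Pat1	common	MSN	missense	Val268Ile	unknown	.
Pat1	common	MYT1L	missense	Ser696Asn	unknown	.
Pat1	common	SRC	frameshift	Thr524HisfsTer52	high	Manual review
Pat2	common	EPHA2	missense	Arg861Cys	high	known mutation
Pat2	common	IDH2	missense	Arg172Trp	high	known mutation
Pat2	common	DNAH11	missense	Glu1074Lys	putative	<= 5 AA to known mutation
Pat2	common	MUC16	missense	Arg2736Trp	putative	<= 5 AA to known mutation
Pat3	common	IDH1	missense	Arg132Cys	high	known mutation
Pat3	common	MUC16	missense	Thr2087Met	putative	<= 5 AA to known mutation
Pat3	common	BAP1	splice_site	NA	unknown	.
Pat3	common	EPHA2	nonsense	Cys262Ter	unknown	.
Pat4	private_peripheral	MSH6	missense	Arg33Cys	putative	<= 5 AA to known mutation
Pat4	common	BAP1	frameshift	Asn133GlnfsTer10	putative	<= 5 AA to known mutation
Pat4	common	DNAH9	missense	Phe4464Ser	unknown	.
Pat4	common	GNA14	splice_site	NA	unknown	.
Pat4	common	PTPRC	missense	Gln407Lys	unknown	.
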