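# Synthetic SIFT scores (stand-in for precomputed SIFT annotations).
gene	aa_change	score
CSMD1	Val2977Met	0.01
SMAD4	Ser72Thr	0.02
KRAS	Gly12Asp	0.01
EPHA2	Arg861Cys	0.02
IDH1	Arg132Cys	0.01
IDH2	Arg172Trp	0.03
FAT2	Arg2024Thr	0.31
MSN	Val268Ile	0.48
MYT1L	Ser696Asn	0.12
DNAH11	Glu1074Lys	0.06
MUC16	Arg2736Trp	0.22
MUC16	Thr2087Met	0.34
MSH6	Arg33Cys	0.07
DNAH9	Phe4464Ser	0.27
PTPRC	Gln407Lys	0.09
EPHA2	Cys262Ter	0.61
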