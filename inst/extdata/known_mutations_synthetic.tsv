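# Synthetic known-mutation set (stand-in for COSMIC amino-acid-level
# records); positions chosen so the published driver table re-derives its
# printed tiers.
gene	aa_position	aa_change
KRAS	12	Gly12Asp
EPHA2	861	Arg861Cys
IDH2	172	Arg172Trp
IDH1	132	Arg132Cys
DNAH11	1070	Glu1070Lys
MUC16	2739	Arg2739Trp
MUC16	2085	Thr2085Met
MSH6	38	Arg38His
BAP1	130	Gln130Ter
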