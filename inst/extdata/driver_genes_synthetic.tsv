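# Synthetic driver gene list: a constructed stand-in for the study's
# curated selection (recurrently mutated iCCA genes, COSMIC >=3% biliary
# tract, COSMIC cancer gene census). Not a COSMIC extract.
gene	source
KRAS	recurrent_iCCA_study
IDH1	recurrent_iCCA_study
IDH2	recurrent_iCCA_study
BAP1	recurrent_iCCA_study
SMAD4	recurrent_iCCA_study
EPHA2	recurrent_iCCA_study
EPHA2	cancer_gene_census
CSMD1	cosmic_ge3pct_biliary
FAT2	cosmic_ge3pct_biliary
MYT1L	cosmic_ge3pct_biliary
DNAH11	cosmic_ge3pct_biliary
MUC16	cosmic_ge3pct_biliary
DNAH9	cosmic_ge3pct_biliary
GNA14	cosmic_ge3pct_biliary
MSN	cancer_gene_census
PTPRC	cancer_gene_census
MSH6	cancer_gene_census
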