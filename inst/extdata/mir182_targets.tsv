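mirna_id	gene_symbol	evidence	db_origin
hsa-miR-182-5p	DHCR7	lipid-metabolism	miRTarBase
hsa-miR-182-5p	HMGCS1	lipid-metabolism	miRTarBase
hsa-miR-182-5p	INSIG1	lipid-metabolism	miRTarBase
hsa-miR-182-5p	SCD	lipid-metabolism	miRTarBase
hsa-miR-182-5p	FASN	lipid-metabolism	miRTarBase
hsa-miR-182-5p	ELOVL6	lipid-metabolism	miRTarBase
hsa-miR-182-5p	ACACA	lipid-metabolism	miRTarBase
hsa-miR-182-5p	PNPLA2	lipid-metabolism	miRTarBase
hsa-miR-182-5p	PPARA	lipid-metabolism	TarBase
hsa-miR-182-5p	LRP6	lipid-metabolism	TarBase
hsa-miR-182-5p	PDK1	glucose-homeostasis	miRTarBase
hsa-miR-182-5p	INSR	glucose-homeostasis	miRTarBase
hsa-miR-182-5p	IRS1	glucose-homeostasis	miRTarBase
hsa-miR-182-5p	FOXO1	glucose-homeostasis	miRTarBase
hsa-miR-182-5p	G6PC	glucose-homeostasis	TarBase
hsa-miR-182-5p	PCK1	glucose-homeostasis	TarBase
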