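EGFR_TKI_RESISTANCE	synthetic pathway set	IGF1R	IGF1	IGF2	ERBB2	ERBB3	MTOR	PTEN	BCL2	VEGFA	MYC
EMT_REGULATION	synthetic pathway set	ZEB1	ZEB2	SNAI1	VEGFA	APC
APOPTOSIS_CORE	synthetic pathway set	BCL2	MYC	PTEN
WNT_SIGNALING	synthetic pathway set	APC	MYC
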