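miRTarBase ID	miRNA	Species (miRNA)	Target Gene	Species (Target Gene)	Experiments	Support Type	References (PMID)
SYN0001	hsa-miR-200a-3p	Homo sapiens	ZEB1	Homo sapiens	Luciferase reporter assay;Western blot;qRT-PCR	Functional MTI	10000001
SYN0002	hsa-miR-200b-3p	Homo sapiens	ZEB1	Homo sapiens	Luciferase reporter assay;Western blot;qRT-PCR	Functional MTI	10000002
SYN0003	hsa-miR-429	Homo sapiens	ZEB1	Homo sapiens	Luciferase reporter assay;Western blot;qRT-PCR	Functional MTI	10000003
SYN0004	hsa-miR-141-3p	Homo sapiens	ZEB2	Homo sapiens	Luciferase reporter assay;Western blot;qRT-PCR	Functional MTI	10000004
SYN0005	hsa-miR-200b-3p	Homo sapiens	ZEB2	Homo sapiens	Luciferase reporter assay;Western blot;qRT-PCR	Functional MTI	10000005
SYN0006	hsa-miR-429	Homo sapiens	ZEB2	Homo sapiens	Western blot;qRT-PCR;Luciferase reporter assay	Functional MTI	10000006
SYN0007	hsa-miR-145-5p	Homo sapiens	IGF1R	Homo sapiens	Luciferase reporter assay;Western blot;qRT-PCR	Functional MTI	10000007
SYN0008	hsa-miR-100-5p	Homo sapiens	IGF1R	Homo sapiens	Luciferase reporter assay;Western blot;qRT-PCR	Functional MTI	10000008
SYN0009	hsa-miR-99a-5p	Homo sapiens	IGF1R	Homo sapiens	Luciferase reporter assay;Western blot;qRT-PCR	Functional MTI	10000009
SYN0010	hsa-miR-143-3p	Homo sapiens	IGF1R	Homo sapiens	Luciferase reporter assay;Western blot;qRT-PCR	Functional MTI	10000010
SYN0011	hsa-let-7c-5p	Homo sapiens	IGF1R	Homo sapiens	Luciferase reporter assay;Western blot;qRT-PCR	Functional MTI	10000011
SYN0012	hsa-miR-133a-3p	Homo sapiens	IGF1R	Homo sapiens	Luciferase reporter assay;Western blot;qRT-PCR	Functional MTI	10000012
SYN0013	hsa-miR-376a-3p	Homo sapiens	IGF1R	Homo sapiens	Luciferase reporter assay;Western blot;qRT-PCR	Functional MTI	10000013
SYN0014	hsa-miR-195-5p	Homo sapiens	BCL2	Homo sapiens	Luciferase reporter assay;Western blot;qRT-PCR	Functional MTI	10000014
SYN0015	hsa-miR-497-5p	Homo sapiens	BCL2	Homo sapiens	Luciferase reporter assay;Western blot;qRT-PCR	Functional MTI	10000015
SYN0016	hsa-miR-125b-5p	Homo sapiens	BCL2	Homo sapiens	Luciferase reporter assay;Western blot;qRT-PCR	Functional MTI	10000016
SYN0017	hsa-miR-195-5p	Homo sapiens	VEGFA	Homo sapiens	Luciferase reporter assay;Western blot;qRT-PCR	Functional MTI	10000017
SYN0018	hsa-miR-497-5p	Homo sapiens	VEGFA	Homo sapiens	Luciferase reporter assay;Western blot;qRT-PCR	Functional MTI	10000018
SYN0019	hsa-miR-126-3p	Homo sapiens	VEGFA	Homo sapiens	Luciferase reporter assay;Western blot;qRT-PCR	Functional MTI	10000019
SYN0020	hsa-miR-29c-3p	Homo sapiens	VEGFA	Homo sapiens	Luciferase reporter assay;Western blot;qRT-PCR	Functional MTI	10000020
SYN0021	hsa-miR-19a-3p	Homo sapiens	PTEN	Homo sapiens	Luciferase reporter assay;Western blot;qRT-PCR	Functional MTI	10000021
SYN0022	hsa-miR-106b-5p	Homo sapiens	PTEN	Homo sapiens	Luciferase reporter assay;Western blot;qRT-PCR	Functional MTI	10000022
SYN0023	hsa-miR-20a-5p	Homo sapiens	PTEN	Homo sapiens	Luciferase reporter assay;Western blot;qRT-PCR	Functional MTI	10000023
SYN0024	hsa-miR-135b-5p	Homo sapiens	APC	Homo sapiens	Luciferase reporter assay;Western blot;qRT-PCR	Functional MTI	10000024
SYN0025	hsa-miR-135b-5p	Homo sapiens	MYC	Homo sapiens	qRT-PCR	Functional MTI (Weak)	10000025
SYN0026	hsa-miR-19a-3p	Homo sapiens	MYC	Homo sapiens	Western blot	Functional MTI (Weak)	10000026
SYN0027	hsa-miR-145-5p	Homo sapiens	SNAI1	Homo sapiens	Luciferase reporter assay;Western blot;qRT-PCR	Functional MTI	10000027
SYN0028	hsa-miR-145-5p	Homo sapiens	IGF1	Homo sapiens	Luciferase reporter assay;Western blot;qRT-PCR	Functional MTI	10000028
SYN0029	hsa-miR-100-5p	Homo sapiens	IGF2	Homo sapiens	Luciferase reporter assay;Western blot;qRT-PCR	Functional MTI	10000029
SYN0030	hsa-miR-125b-5p	Homo sapiens	ERBB2	Homo sapiens	Luciferase reporter assay;Western blot;qRT-PCR	Functional MTI	10000030
SYN0031	hsa-miR-125b-5p	Homo sapiens	ERBB3	Homo sapiens	Luciferase reporter assay;Western blot;qRT-PCR	Functional MTI	10000031
SYN0032	hsa-miR-99a-5p	Homo sapiens	MTOR	Homo sapiens	Luciferase reporter assay;Western blot;qRT-PCR	Functional MTI	10000032
SYN0033	hsa-miR-100-5p	Homo sapiens	MTOR	Homo sapiens	Luciferase reporter assay;Western blot;qRT-PCR	Functional MTI	10000033
SYN0034	mmu-miR-21a-5p	Mus musculus	Pten	Mus musculus	Luciferase reporter assay;Western blot;qRT-PCR	Functional MTI	10000034
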