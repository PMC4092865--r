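pathway	symbol
PI3K_AKT	HER2
PI3K_AKT	HER3
PI3K_AKT	NRG4
PI3K_AKT	NRG1
PI3K_AKT	AKT1
PI3K_AKT	PIK3R2
PI3K_AKT	FOXO1
PI3K_AKT	FOXO3
PI3K_AKT	HBEGF
PI3K_AKT	FGFR3
PI3K_AKT	VEGFB
PI3K_AKT	SYK
PI3K_AKT	LAMC3
PI3K_AKT	RAC1
PI3K_AKT	JUN
PI3K_AKT	CDKN1A
PI3K_AKT	CDKN2A
PI3K_AKT	TGFA
PI3K_AKT	IGF1
PI3K_AKT	EPHA2
PI3K_AKT	PDGFRA
PI3K_AKT	JAK1
PI3K_AKT	SRC
PI3K_AKT	TEK
PI3K_AKT	LAMB1
PI3K_AKT	LAMC1
PI3K_AKT	PDK3
PI3K_AKT	IL6R
PI3K_AKT	GPX2
PI3K_AKT	KIT
PI3K_AKT	KITLG
PI3K_AKT	OSMR
PI3K_AKT	GSK3B
PI3K_AKT	MYC
ERK1_2	HER2
ERK1_2	HER3
ERK1_2	HSPB1
ERK1_2	APOBEC2
ERK1_2	APOBEC3B
ERK1_2	APOBEC3F
ERK1_2	APOBEC3H
ERK1_2	CACNG5
ERK1_2	CACNA1H
ERK1_2	CACNA1B
ERK1_2	CACNG8
ERK1_2	CACNA2D2
ERK1_2	CACNA2D3
ERK1_2	MAPK1
ERK1_2	MAPK4
ERK1_2	MAPK10
ERK1_2	ARAF
ERK1_2	LRIG1
ERK1_2	RASGRP3
ERK1_2	RAP1B
ERK1_2	RRAS2
ERK1_2	APOL3
ERK1_2	APOL6
ERK1_2	APOE
ERK1_2	YWHAB
ERK1_2	FOS
ERK1_2	JUNB
ERK1_2	THBS1
ERK1_2	LAMC2
ERK1_2	LAMB3
ERK1_2	IFNAR2
ERK1_2	SFN
ERK1_2	DUSP1
ERK1_2	DUSP4
ERK1_2	DUSP6
ERK1_2	IL6
ERK1_2	IL1A
ERK1_2	BCL6
ERK1_2	ELK3
ERK1_2	FOSL1
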