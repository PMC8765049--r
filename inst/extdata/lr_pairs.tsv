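pair_id	ligand	receptor	annotation
TNF_TNFRSF1A	TNF	TNFRSF1A	TNF signaling
TNF_TNFRSF1B	TNF	TNFRSF1B	TNF signaling
TNFSF10_TNFRSF10A	TNFSF10	TNFRSF10A	TRAIL apoptosis
TNFSF10_TNFRSF10B	TNFSF10	TNFRSF10B	TRAIL apoptosis
TGFB1_TGFBR1	TGFB1	TGFBR1	TGF-beta signaling
TGFB1_TGFBR1_TGFBR2	TGFB1	TGFBR1;TGFBR2	TGF-beta receptor complex
COL1A1_a1b1	COL1A1	ITGA1;ITGB1	collagen to integrin a1b1 complex
COL1A2_a1b1	COL1A2	ITGA1;ITGB1	collagen to integrin a1b1 complex
COL4A1_a1b1	COL4A1	ITGA1;ITGB1	collagen to integrin a1b1 complex
COL6A2_a1b1	COL6A2	ITGA1;ITGB1	collagen to integrin a1b1 complex
CXCL12_CXCR4	CXCL12	CXCR4	chemokine axis
CCL3_CCR5	CCL3	CCR5	chemokine axis
CCL4_CCR5	CCL4	CCR5	chemokine axis
CCL2_CCR2	CCL2	CCR2	monocyte recruitment
CXCL9_CXCR3	CXCL9	CXCR3	T cell recruitment
CXCL10_CXCR3	CXCL10	CXCR3	T cell recruitment
IL10_IL10RA	IL10	IL10RA	immunosuppressive cytokine
IL6_IL6R	IL6	IL6R	inflammatory cytokine
IL1B_IL1R1	IL1B	IL1R1	inflammatory cytokine
IFNG_IFNGR1_IFNGR2	IFNG	IFNGR1;IFNGR2	interferon-gamma receptor complex
CD274_PDCD1	CD274	PDCD1	PD-L1 checkpoint
PDCD1LG2_PDCD1	PDCD1LG2	PDCD1	PD-L2 checkpoint
CD80_CTLA4	CD80	CTLA4	B7 checkpoint
CD86_CTLA4	CD86	CTLA4	B7 checkpoint
LGALS9_HAVCR2	LGALS9	HAVCR2	TIM-3 axis
VEGFA_KDR	VEGFA	KDR	angiogenesis
VEGFA_FLT1	VEGFA	FLT1	angiogenesis
EGF_EGFR	EGF	EGFR	growth factor
HGF_MET	HGF	MET	growth factor
FN1_a5b1	FN1	ITGA5;ITGB1	fibronectin to integrin a5b1
CSF1_CSF1R	CSF1	CSF1R	macrophage survival
MIF_CD74	MIF	CD74	MIF axis
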