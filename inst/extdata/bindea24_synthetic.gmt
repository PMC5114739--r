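aDC	reconstructed_immune_cell_signature	CCL1	EBI3	IDO1	LAMP3	OAS3
B cells	reconstructed_immune_cell_signature	ABCB4	BACH2	BCL11A	BLK	BLNK	CCR9	CD19	CD72	COCH	CR2	DTNB	FCRL2	GLDC	GNG7	HLA-DOB	IGHA1	IGHG1	IGHM	IGKC	IGLJ3	KIAA0125	MEF2C	MICAL3	MS4A1	OSBPL10	PNOC	QRSL1	SCN3A	SLC15A2	SPIB	TCL1A	TNFRSF17	CD79A	CD79B	PAX5	EBF1	VPREB3	FCRLA	FCRL1	CD22	FCER2	CD40	BANK1	CD24	TLR10	STAP1	P2RX5	POU2AF1	IGLL1	AFF3	CXCR5	HVCN1	TNFRSF13B	TNFRSF13C	RALGPS2	FAM129C	TCL1B	FCRL5	CD37	SWAP70
CD8 T cells	reconstructed_immune_cell_signature	ABT1	AES	APBA2	ARHGAP8	C12orf47	C19orf6	CAMLG	CD8A	CD8B	CDKN2AIP	DNAJB1	EOMES	FLT3LG	GADD45A	GZMM	KLF9	LEPROTL1	LIME1	MYST3	PF4	PPP1R2	PRF1	PRR5	RBM3	SF1	SFRS7	SLC16A7	TBCC	THUMPD1	TMC6	TSC22D3	VAMP2	ZEB1	ZFP36L2	ZNF22	ZNF609	ZNF91
Cytotoxic cells	reconstructed_immune_cell_signature	APBA2	APOL3	CTSW	DUSP2	FASLG	GNLY	GZMA	GZMB	GZMH	GZMK	KLRB1	KLRD1	KLRF1	KLRG1	KLRK1	NKG7	RORA	RUNX3	SIGIRR	WHAMMP3	ZBTB16
DC	reconstructed_immune_cell_signature	CCL13	CCL17	CCL22	CD209	HSD11B1	NPR1	PPFIBP2
Eosinophils	reconstructed_immune_cell_signature	ABHD2	ACACB	CAT	CCR3	CLC	CYSLTR2	EMR1	EPN2	GALC	HES1	HIST1H1C	HRH4	IL5RA	KBTBD11	KCNH2	LRP5L	MYO15B	RCOR3	RNASE2	RRP12	SIAH1	SMPD3	SYNJ1	TGIF1	THBS1	THBS4
iDC	reconstructed_immune_cell_signature	ABCG2	BLVRB	CARD9	CD1A	CD1B	CD1C	CD1E	CH25H	CSF1R	CTNS	F13A1	FABP4	FZD2	GSTT1	HS3ST2	MMP12	NUDT9	PPARG	PREP	SLC26A6	SLC7A8	SYT17	TACSTD2	TM7SF4	VASH1
Macrophages	reconstructed_immune_cell_signature	APOE	ATG7	BCAT1	CCL7	CD163	CD68	CD84	CHI3L1	CHIT1	CLEC5A	COL8A2	COLEC12	CTSK	CXCL5	CYBB	DNASE2B	EMP1	FDX1	FN1	GM2A	GPC4	KAL1	MARCO	ME1	MS4A4A	MSR1	PCOLCE2	PTGDS	RAI14	SCARB2	SCG5	SGMS1	SULT1C2
Mast cells	reconstructed_immune_cell_signature	ABCC4	ADCYAP1	CALB2	CEACAM8	CMA1	CPA3	CTSG	ELA2	GATA2	HDC	HPGD	HPGDS	KIT	MAOB	MLPH	MPO	MS4A2	NR0B1	PPM1H	PRG2	PTGS1	SCG2	SIGLEC6	SLC18A2	SLC24A3	TAL1	TPSAB1	TPSB2	VWA5A
Neutrophils	reconstructed_immune_cell_signature	ALPL	BST1	CD93	CEACAM3	CREB5	CRISPLD2	CSF3R	CYP4F3	DYSF	FCAR	FCGR3B	FPR1	FPR2	G0S2	HIST1H2BC	HPSE	IL8RA	IL8RB	KCNJ15	LILRB2	MGAM	MME	PDE4B	S100A12	SIGLEC5	SLC22A4	SLC25A37	TECPR2	TNFRSF10C	VNN3
NK CD56bright cells	reconstructed_immune_cell_signature	DUSP4	FOXJ1	MADD	MPPED1	MUC3B	PLA2G6	RRAD	XCL1
NK CD56dim cells	reconstructed_immune_cell_signature	GTF3C1	GZMB	IL21R	KIR2DL3	KIR2DS1	KIR2DS2	KIR2DS5	KIR3DL1	KIR3DL2	KIR3DL3	KIR3DS1	S1PR5	SPON2
NK cells	reconstructed_immune_cell_signature	ADARB1	ALDH1B1	BCL2	CD244	CDC5L	FCGR3A	FGF18	FUT5	FZR1	IGFBP5	KIR2DL1	KIR2DL4	KLRB1	KLRC1	KLRC2	KLRC3	LDB3	MAPRE3	MCM3AP	NCAM1	NCR1	NCR2	NCR3	PSMD4	SH2D1B	SLC30A5	SPN	SPON2	TBXA2R	TINAGL1	TTC38	XCL1	XCL2	ZMAT4	ZNF205
pDC	reconstructed_immune_cell_signature	IL3RA
T cells	reconstructed_immune_cell_signature	BCL11B	CD2	CD28	CD3D	CD3E	CD3G	CD5	CD6	CD96	FLT3LG	GIMAP5	IL7R	ITM2A	LCK	NCALD	PRKCQ	SH2D1A	SKAP1	THEMIS	TRAT1	TRBC1	UBASH3A
T helper cells	reconstructed_immune_cell_signature	ANP32B	ASF1A	ATF2	BATF	CD4	CD40LG	DDX50	FAM111A	FRYL	GATA3	GOLGA8A	ICOS	ITK	LRBA	NAP1L4	NUP107	PHF10	PPP2R5C	SEC24C	SLC25A12	SRSF10	TNFSF8	UBE2L3	YME1L1
Tcm	reconstructed_immune_cell_signature	AQP3	ATF7IP	ATM	CASP8	CCR7	CDC14A	CLUAP1	CREBZF	CYLD	DOCK9	FAM153B	FOXP1	FYB	HNRNPH1	INPP4B	KLF12	LEF1	MAP3K1	MLL	NEFL	NFATC3	PCM1	PCNX	PHC3	PSPC1	REPS1	RPP38	SELL	SLC7A6	SNRPN	ST3GAL1	STX16	TIMM8A	TRAF3IP3	TXK	USP9Y
Tem	reconstructed_immune_cell_signature	AKT3	ANXA1	CCL5	CCR2	CD58	CXCR3	DDX17	EWSR1	EZR	FLI1	GDPD5	GPR183	IL32	KLF6	LTK	MEFV	NFATC4	PRKY	S100A4	TBCD
Tfh	reconstructed_immune_cell_signature	B3GAT1	CDK5R1	CHGB	HEY1	HIST1H4K	ICOS	KCNK5	KIAA1324	MAF	MKL2	MYO6	MYO7A	PASK	PDCD1	POMT1	PTPN13	PVALB	SH3TC1	SLC7A10	SMAD1	ST8SIA1	STK39	THADA	TOX	TSHR
Tgd	reconstructed_immune_cell_signature	C1orf61	CD160	FEZ1	TARP	TRDC	TRGV9
Th1 cells	reconstructed_immune_cell_signature	APBB2	APOD	ATP9A	BTG3	CD38	CD70	CMAH	CSF2	CTLA4	DGKI	DOK5	DPP4	DUSP5	EGFL6	GGT1	HBEGF	IFNG	IL12RB2	IL22	LRP8	LRRN3	LTA	SGCB	SYNGR3	ZBTB32
Th17 cells	reconstructed_immune_cell_signature	IL17A	RORC
Th2 cells	reconstructed_immune_cell_signature	ADCY1	AHI1	ANK1	BIRC5	CDC25C	CDC7	CENPF	CXCR6	DHFR	EVI5	GATA3	GSTA4	HELLS	IL26	LAIR2	LIMA1	MB	MICAL2	NEIL3	PHEX	PMCH	PTGIS	SLC39A14	SMAD2	SNRPD1	WDHD1
Treg	reconstructed_immune_cell_signature	FOXP3
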