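Angiogenesis	reconstructed_angiogenesis_signature	ANGPT2	APLN	CAV1	CD34	CD93	CDH5	CLEC14A	CXorf36	ECSCR	EGFL7	ELTD1	EMCN	ENG	ERG	ESAM	ESM1	FLT1	FLT4	GPR116	ICAM2	JAM2	KDR	MMRN2	MYCT1	NOS3	NOTCH4	PECAM1	PLVAP	PTPRB	RAMP2	RAMP3	RHOJ	ROBO4	S1PR1	SOX18	SPARCL1	TEK	TIE1	TM4SF18	VWF
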