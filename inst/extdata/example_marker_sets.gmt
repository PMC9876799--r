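NK cells	synthetic example base set	XCL1	XCL2	NCR1
NK CD56dim cells	synthetic example base set	IL21R	KIR2DL3	KIR3DL1	KIR3DL2
Cytotoxic cells	synthetic example base set	GZMA	GZMB	GZMH	PRF1	GNLY	CTSW	KLRB1	KLRD1
CD8 T cells	synthetic example base set	CD8A	CD8B
T cells	synthetic example base set	CD3D	CD3E	CD3G	CD2
B cells	synthetic example base set	CD19	MS4A1	CD79A
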