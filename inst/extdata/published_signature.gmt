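shared_ur_top	published top shared-UR list	COL1A1	FN1	SPP1	COL4A1	COL18A1	PLAU	CLEC11A	MDK
mcaf_marker	published matrix-CAF marker list	MMP11	CTHRC1	COL1A2	COL3A1	SPARC	COL5A2	POSTN	COL11A1
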