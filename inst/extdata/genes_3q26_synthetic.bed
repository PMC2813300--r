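chr3	180300000	180390000	PIK3CA
chr3	181950000	182010000	FXR1
chr3	182200000	182206000	DNAJC19
chr3	182500000	182530000	B3GNT5
chr3	182700000	182800000	MCCC1
chr3	183300000	183340000	LAMP3
chr3	183500000	184200000	SOX2OT
chr3	183990000	183992500	SOX2
chr3	184250000	184380000	ATP11B
chr3	184450000	184490000	DCUN1D1
chr3	191000000	191270000	TP63
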