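EXHAUSTION_UP_SYNTHETIC	Synthetic chronic-stimulation T-cell exhaustion signature: inhibitory receptors, exhaustion TFs and chemokines (stand-in list, substitute any GMT)	LAG3	HAVCR2	CTLA4	TIGIT	TBX21	IFNG	CCL1	CCL3	CCL4	CCL5	ENTPD1	PDCD1	TOX	EOMES	CD160	CD244	CD38	CD101	CXCL13	PRDM1	NR4A2	VSIR	CD27	PTGER4
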