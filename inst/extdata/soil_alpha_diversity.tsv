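earthworm	otn_shannon	otu_shannon	otn_simpson	otu_simpson
yes	5.49	5.12	120.2	93.03
yes	5.41	4.97	94.68	70.55
yes	5.48	5.03	117.6	71.63
no	5.61	5.13	143.3	94.92
no	5.55	5.21	147.1	104.83
no	5.52	5.29	151.5	131.55
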