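locus_id	northern_detectable	c2_nb	c3_nb
ddi-miR-1176	1	0	0
ddi-miR-1177	1	0	0
miRNA_can_D1	1	0	0
miRNA_can_D2	1	0	0
ddi-mir-7097	1	0	0
miRNA_can_D3	1	0	0
miRNA-like_D4	1	1	1
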