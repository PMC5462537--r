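##gff-version 3
chr5	poolscan	gene	101	660	.	+	.	ID=gene:cx34.1-like
chr5	poolscan	mRNA	101	660	.	+	.	ID=tx_cx34.1-like;Parent=gene:cx34.1-like
chr5	poolscan	exon	101	179	.	+	.	Parent=tx_cx34.1-like
chr5	poolscan	exon	380	660	.	+	.	Parent=tx_cx34.1-like
chr5	poolscan	CDS	101	179	.	+	0	ID=cds_cx34.1-like;Parent=tx_cx34.1-like
chr5	poolscan	CDS	380	660	.	+	0	ID=cds_cx34.1-like;Parent=tx_cx34.1-like
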