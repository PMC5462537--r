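##fileformat=VCFv4.2
##reference=synthetic_cx_locus.fa
##contig=<ID=chr5,length=760>
#CHROM	POS	ID	REF	ALT	QUAL	FILTER	INFO
chr5	40	.	T	A	.	PASS	.
chr5	170	.	C	A	.	PASS	.
chr5	279	.	A	C	.	PASS	.
chr5	424	.	T	A	.	PASS	.
chr5	546	.	T	A	.	PASS	.
chr5	730	.	T	A	.	PASS	.
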