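##fileformat=VCFv4.2
##source=precisebe
##contig=<ID=chrS>
#CHROM	POS	ID	REF	ALT	QUAL	FILTER	INFO
chrS	100	.	C	T	.	PASS	.
chrS	200	.	G	A	.	PASS	.
chrS	300	.	T	C	.	PASS	.
chrS	400	.	C	T	.	PASS	.
chrS	500	.	G	A	.	PASS	.
chrS	600	.	A	G	.	PASS	.
chrS	700	.	G	A	.	PASS	.
chrS	800	.	C	CC	.	PASS	.
chrS	900	.	G	A	.	PASS	.
chrS	1000	.	AC	A	.	PASS	.
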