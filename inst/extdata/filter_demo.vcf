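##fileformat=VCFv4.2
##FORMAT=<ID=AD,Number=R,Type=Integer,Description="Allelic depths (ref,alt)">
##contig=<ID=Chr1>
#CHROM	POS	ID	REF	ALT	QUAL	FILTER	INFO	FORMAT	red_parent	green_parent	original	red_pool	green_pool
Chr1	1000	.	A	T,G	.	PASS	.	AD	10,5,5	20,0,0	14,0,0	12,6,6	22,0,0
Chr1	2000	.	C	T	.	PASS	.	AD	9,8	18,0	15,0	2,1	25,0
Chr1	3000	.	G	A	.	PASS	.	AD	11,9	21,0	16,0	20,0	22,0
Chr1	4000	.	T	C	.	PASS	.	AD	12,7	15,0	13,0	12,0	10,6
Chr1	5000	.	A	C	.	PASS	.	AD	10,8	18,0	14,0	12,10	20,0
Chr1	6000	.	C	G	.	PASS	.	AD	9,9	22,0	16,0	14,11	24,0
Chr1	7000	.	GAT	G	.	PASS	.	AD	11,7	19,0	12,0	13,9	21,0
Chr1	8000	.	T	TCA	.	PASS	.	AD	8,10	17,0	15,0	11,12	19,0
Chr1	9000	.	G	C	.	PASS	.	AD	12,8	20,0	13,0	15,10	23,0
Chr1	10000	.	A	G	.	PASS	.	AD	10,9	16,0	14,0	12,11	18,0
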