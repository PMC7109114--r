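##fileformat=VCFv4.2
##FORMAT=<ID=AD,Number=R,Type=Integer,Description="Allelic depths (ref,alt)">
##contig=<ID=Chr4>
#CHROM	POS	ID	REF	ALT	QUAL	FILTER	INFO	FORMAT	ZaosuRed	Zaosu	KualaPear	GreenPool	RedPool
Chr4	8553091	.	C	TTC	.	PASS	.	AD	2,4	0,3	0,2	0,6	6,7
Chr4	9115802	.	T	A	.	PASS	.	AD	0,5	.	7,0	11,0	7,6
Chr4	9121649	.	G	TG	.	PASS	.	AD	5,4	5,0	17,0	28,0	19,4
Chr4	9122408	.	G	GA	.	PASS	.	AD	11,4	8,0	7,0	20,0	20,8
Chr4	9178944	.	T	AGAT	.	PASS	.	AD	2,5	2,0	3,0	5,0	6,1
Chr4	9212167	.	C	T	.	PASS	.	AD	0,1	.	2,0	6,0	5,4
Chr4	9212608	.	G	T	.	PASS	.	AD	0,8	.	7,0	15,0	10,7
Chr4	9214082	.	T	C	.	PASS	.	AD	0,3	.	8,0	9,0	12,1
Chr4	9214271	.	A	G	.	PASS	.	AD	0,4	.	8,0	11,0	12,2
Chr4	9222351	.	T	TA	.	PASS	.	AD	11,4	8,0	11,0	27,0	14,5
Chr4	9222379	.	G	GT	.	PASS	.	AD	12,4	11,0	12,0	28,0	17,6
Chr4	16860274	.	A	GA	.	PASS	.	AD	18,9	9,0	7,0	13,0	17,7
Chr4	18388296	.	AGCAGCTGAAGTTCC	A	.	PASS	.	AD	10,5	14,0	20,0	39,0	24,9
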