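##fileformat=VCFv4.3
##reference=synthetic
##contig=<ID=1>
##contig=<ID=2>
##INFO=<ID=DP,Number=1,Type=Integer,Description="Total depth">
#CHROM	POS	ID	REF	ALT	QUAL	FILTER	INFO
1	10177	rs81002812	G	A	50	PASS	DP=20
1	20763	rs199473684	G	A,C	99	PASS	DP=31
2	30421	rs121909551	C	G	77	PASS	.
2	40532	rs555555555	T	C	12	PASS	DP=5
2	50644	.	A	T	8	PASS	DP=3
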