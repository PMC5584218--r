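##fileformat=VCFv4.2
##INFO=<ID=GENE,Number=1,Type=String,Description="Gene symbol">
##INFO=<ID=CSQ,Number=1,Type=String,Description="Consequence class">
##INFO=<ID=AF,Number=A,Type=Float,Description="Population allele frequency">
##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">
##FORMAT=<ID=DP,Number=1,Type=Integer,Description="Read depth">
##FORMAT=<ID=AD,Number=R,Type=Integer,Description="Allelic depths">
##contig=<ID=1,length=249250621>
#CHROM	POS	ID	REF	ALT	QUAL	FILTER	INFO	FORMAT	S001	S002	S003
1	1000	var1	C	T	100	PASS	GENE=GENE1;CSQ=nonsense;AF=0.0004	GT:DP:AD	0/1:520:280,240	0/0:480:475,5	0/0:300:300,0
1	2000	var2	G	A	100	PASS	GENE=GENE1;CSQ=missense;AF=0.002	GT:DP:AD	0/0:260:258,2	0/1:310:160,150	0/0:200:200,0
1	3000	var3	AT	A	100	PASS	GENE=GENE2;CSQ=frameshift_indel;AF=0.0001	GT:DP:AD	0/0:90:90,0	0/0:110:110,0	0/1:22:14,8
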