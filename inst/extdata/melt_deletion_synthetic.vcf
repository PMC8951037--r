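##fileformat=VCFv4.2
##source=synthetic example of MELT Deletion-mode output (reference SINE insertions genotyped as deletions)
##INFO=<ID=SVTYPE,Number=1,Type=String,Description="Type of structural variant">
##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">
##FILTER=<ID=hDP,Description="More than expected discordant pairs">
#CHROM	POS	ID	REF	ALT	QUAL	FILTER	INFO	FORMAT	sppA	sppB	sppC	sppD
chr1	1500	.	T	<DEL:ME:VES>	.	PASS	SVTYPE=VES	GT	0/0	0/0	1/1	1/1
chr1	7000	.	G	<DEL:ME:VES>	.	PASS	SVTYPE=VES	GT	1/1	1/1	0/0	0/0
chr2	2000	.	A	<DEL:ME:VES>	.	hDP	SVTYPE=VES	GT	0/0	1/1	1/1	1/1
chr2	4400	.	C	<DEL:ME:VES>	.	PASS	SVTYPE=VES	GT	0/1	1/1	0/0	./.
chr2	5100	.	A	<DEL:ME:VES>	.	PASS	SVTYPE=VES	GT	0/0	0/0	0/0	1/1
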