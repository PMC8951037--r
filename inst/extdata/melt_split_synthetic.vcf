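##fileformat=VCFv4.2
##source=synthetic example of MELT Split-mode output (non-reference SINE insertions)
##INFO=<ID=ASSESS,Number=1,Type=Integer,Description="Provides information on evidence availability to decide insertion site">
##INFO=<ID=SVTYPE,Number=1,Type=String,Description="Type of structural variant">
##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">
##FILTER=<ID=lc,Description="MEI is embedded in a low complexity region">
#CHROM	POS	ID	REF	ALT	QUAL	FILTER	INFO	FORMAT	sppA	sppB	sppC	sppD
chr1	1000	.	T	<INS:ME:VES>	.	PASS	ASSESS=5;SVTYPE=VES	GT	0/1	1/1	0/0	0/0
chr1	2500	.	G	<INS:ME:VES>	.	PASS	ASSESS=3;SVTYPE=VES	GT	1/1	1/1	0/0	0/0
chr1	4000	.	A	<INS:ME:VES>	.	PASS	ASSESS=1;SVTYPE=VES	GT	1/1	0/0	1/1	0/0
chr1	6000	.	C	<INS:ME:VES>	.	lc	ASSESS=5;SVTYPE=VES	GT	1/1	1/1	1/1	0/0
chr2	1200	.	T	<INS:ME:VES>	.	PASS	ASSESS=4;SVTYPE=VES	GT	0/0	1/1	1/1	./.
chr2	3300	.	G	<INS:ME:VES>	.	PASS	ASSESS=2;SVTYPE=VES	GT	1/1	0/1	0/0	1/1
chr2	5100	.	A	<INS:ME:VES>	.	PASS	ASSESS=5;SVTYPE=VES	GT	0/0	0/0	1/1	1/1
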