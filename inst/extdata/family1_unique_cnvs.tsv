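chrom	start	end	cytoband	size_bp	cnv_type	identity	genes
chr5	119380128	119382128	5q23.1	2000	del	de_novo	
chr9	6700000	6710000	9p24.1	10000	del	de_novo	
chr10	26998675	27002675	10p12.1	4000	del	de_novo	PDSS1
chr14	20314000	20328000	14q11.2	14000	amp	inherited	
chr15	22422114	22492114	15q11.2	70000	amp	de_novo	LOC642131
chr16	34467150	34515150	16p11.2	48000	amp	de_novo	
chr16	55841801	55855801	16q12.2	14000	amp	inherited	CES1
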