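chrom	start	end	cytoband	size_bp	cnv_type	genes
chr5	17612657	17620657	5p15.1	8000	del	
chr5	46244657	46246657	5p11	2000	amp	
chr5	135114128	135120128	5q31.1	6000	del	
chr12	114521470	114529470	12q24.21	8000	amp	
chr14	106926000	106930000	14q32.33	4000	amp	
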