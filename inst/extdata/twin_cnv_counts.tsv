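sample	family	status	total	shared	unshared	unshared_inherited	unshared_de_novo
I-2-1	1	affected	152	145	7	2	5
I-2-2	1	unaffected	154	145	9	5	4
II-2-1	2	affected	156	151	5	NA	NA
II-2-2	2	unaffected	157	151	6	NA	NA
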