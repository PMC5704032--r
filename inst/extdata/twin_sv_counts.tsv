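sample	family	status	total	shared	unshared	shared_inherited	shared_de_novo	unshared_inherited	unshared_de_novo
I-2-1	1	affected	919	781	138	750	31	97	41
I-2-2	1	unaffected	893	781	112	750	31	66	46
II-2-1	2	affected	996	855	141	NA	NA	NA	NA
II-2-2	2	unaffected	977	855	122	NA	NA	NA	NA
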