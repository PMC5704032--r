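sample	family	status	total	high_conf_unshared	inherited	de_novo
I-2-1	1	affected	4295920	11577	7302	4275
I-2-2	1	unaffected	4265089	9345	5776	3569
II-2-1	2	affected	3780127	10725	NA	NA
II-2-2	2	unaffected	3789298	10351	NA	NA
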