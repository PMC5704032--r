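family	rank	pathway	shared_with	p_value
1	1	CREB signaling in neurons	2A,2U	0.0000041687
1	2	Neuropathic pain signaling in dorsal horn neurons	2A,1U,2U	0.0000083176
1	3	Axonal guidance signaling	2A,1U	0.0000630957
1	4	Cellular effects of sildenafil (Viagra)	2A,1U	0.0001479108
1	5	Role of NFAT in cardiac hypertrophy		0.0001513561
1	6	Dopamine-DARPP32 feedback in cAMP signaling	2A	0.0002290868
1	7	Synaptic long term depression	2A,1U,2U	0.0002398833
1	8	Wnt/Ca+ pathway		0.0003630781
1	9	Synaptic long term potentiation	2A,2U	0.0008511380
1	10	PPARa/RXRa activation	2U	0.0011748976
1	11	Gap junction signaling		0.0013803843
1	12	Glutamate receptor signaling	2A	0.0014791084
1	13	14-3-3-mediated signaling		0.0020417379
1	14	Netrin signaling	2A,1U,2U	0.0022908677
1	15	Leptin signaling in obesity		0.0024547089
1	16	Nitric oxide signaling in the cardiovascular system	2A,1U	0.0024547089
1	17	Hepatic cholestasis	2U	0.0026915348
1	18	Uracil degradation II (reductive)	2U	0.0029512092
1	19	Thymine degradation	2U	0.0029512092
1	20	Melatonin signaling	1U	0.0033113112
2	1	Sperm motility	1U	0.0000053703
2	2	Glutamate receptor signaling	1A	0.0000389045
2	3	Neuropathic pain signaling in dorsal horn neurons	1A,2U,1U	0.0000575440
2	4	Cellular effects of sildenafil (Viagra)	1A,1U	0.0002238721
2	5	Nitric oxide signaling in the cardiovascular system	1A,1U	0.0002884032
2	6	Synaptic long term depression	1A,2U,1U	0.0003235937
2	7	CREB signaling in neurons	1A,2U	0.0003630781
2	8	Synaptic long term potentiation	1A,2U	0.0005888437
2	9	Phospholipase C signaling		0.0008709636
2	10	Netrin signaling	1A,2U,1U	0.0010964782
2	11	G-Protein coupled receptor signaling	2U	0.0012589254
2	12	a-adrenergic signaling		0.0016595869
2	13	Protein kinase A signaling	2U,1U	0.0023442288
2	14	nNOS signaling in neurons		0.0040738028
2	15	Huntington's disease signaling		0.0042657952
2	16	Dopamine-DARPP32 feedback in cAMP signaling	1A	0.0058884366
2	17	Cardiac b-adrenergic signaling	2U	0.0067608298
2	18	Calcium signaling	2U	0.0077624712
2	19	Breast cancer regulation by Stathmin 1		0.0087096359
2	20	Axonal guidance signaling	1A,1U	0.0089125094
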