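pathway	family	gene
Dopamine-DARPP32 feedback in cAMP signaling	1	PRKG2
Dopamine-DARPP32 feedback in cAMP signaling	1	PPP2R1U
Dopamine-DARPP32 feedback in cAMP signaling	1	GUCY1A3
Dopamine-DARPP32 feedback in cAMP signaling	1	PRKAG2
Dopamine-DARPP32 feedback in cAMP signaling	1	ADCY3
Dopamine-DARPP32 feedback in cAMP signaling	1	PRKCB
Dopamine-DARPP32 feedback in cAMP signaling	1	PRKAR1B
Dopamine-DARPP32 feedback in cAMP signaling	1	KCNJ12
Dopamine-DARPP32 feedback in cAMP signaling	1	ADCY2
Dopamine-DARPP32 feedback in cAMP signaling	1	PRKCZ
Dopamine-DARPP32 feedback in cAMP signaling	1	ADCY8
Dopamine-DARPP32 feedback in cAMP signaling	1	PLCL1
Dopamine-DARPP32 feedback in cAMP signaling	1	CACNA1D
Dopamine-DARPP32 feedback in cAMP signaling	1	DRD3
Dopamine-DARPP32 feedback in cAMP signaling	1	PLCB1
Dopamine-DARPP32 feedback in cAMP signaling	1	GUCY1A2
Dopamine-DARPP32 feedback in cAMP signaling	1	EP300
Dopamine-DARPP32 feedback in cAMP signaling	1	PRKG1
Dopamine-DARPP32 feedback in cAMP signaling	1	PPP3CA
Dopamine-DARPP32 feedback in cAMP signaling	1	CACNA1A
Dopamine-DARPP32 feedback in cAMP signaling	1	GRIN2U
Dopamine-DARPP32 feedback in cAMP signaling	1	PLCG2
Dopamine-DARPP32 feedback in cAMP signaling	1	KCNJ3
Dopamine-DARPP32 feedback in cAMP signaling	1	PRKCA
Dopamine-DARPP32 feedback in cAMP signaling	1	PLCH2
Dopamine-DARPP32 feedback in cAMP signaling	1	CACNA1C
Dopamine-DARPP32 feedback in cAMP signaling	1	PLCL2
Dopamine-DARPP32 feedback in cAMP signaling	1	PLCZ1
Dopamine-DARPP32 feedback in cAMP signaling	1	KCNJ10
Dopamine-DARPP32 feedback in cAMP signaling	2	PLCB1
Dopamine-DARPP32 feedback in cAMP signaling	2	PRKG2
Dopamine-DARPP32 feedback in cAMP signaling	2	PRKG1
Dopamine-DARPP32 feedback in cAMP signaling	2	PPM1L
Dopamine-DARPP32 feedback in cAMP signaling	2	CAMK4
Dopamine-DARPP32 feedback in cAMP signaling	2	PLCE1
Dopamine-DARPP32 feedback in cAMP signaling	2	PRKAG2
Dopamine-DARPP32 feedback in cAMP signaling	2	PPP2R2C
Dopamine-DARPP32 feedback in cAMP signaling	2	ADCY10
Dopamine-DARPP32 feedback in cAMP signaling	2	PPP1R14C
Dopamine-DARPP32 feedback in cAMP signaling	2	GRIN2A
Dopamine-DARPP32 feedback in cAMP signaling	2	CREB5
Dopamine-DARPP32 feedback in cAMP signaling	2	PRKCA
Dopamine-DARPP32 feedback in cAMP signaling	2	CACNA1C
Dopamine-DARPP32 feedback in cAMP signaling	2	PRKCB
Dopamine-DARPP32 feedback in cAMP signaling	2	KCNJ12
Dopamine-DARPP32 feedback in cAMP signaling	2	ITPR1
Dopamine-DARPP32 feedback in cAMP signaling	2	PRKAR1B
Dopamine-DARPP32 feedback in cAMP signaling	2	PRKCI
Dopamine-DARPP32 feedback in cAMP signaling	2	PRKCZ
Dopamine-DARPP32 feedback in cAMP signaling	2	ADCY8
Dopamine-DARPP32 feedback in cAMP signaling	2	PRKCG
Dopamine-DARPP32 feedback in cAMP signaling	2	DRD3
Glutamate receptor signaling	1	GRIA1
Glutamate receptor signaling	1	GRIK2
Glutamate receptor signaling	1	GRID1
Glutamate receptor signaling	1	GNB1
Glutamate receptor signaling	1	GRIN2U
Glutamate receptor signaling	1	SLC1A7
Glutamate receptor signaling	1	GRIK1
Glutamate receptor signaling	1	GRIK4
Glutamate receptor signaling	1	GRM7
Glutamate receptor signaling	1	GRM1
Glutamate receptor signaling	1	GRM5
Glutamate receptor signaling	1	GRM8
Glutamate receptor signaling	1	GRIK3
Glutamate receptor signaling	2	GRID1
Glutamate receptor signaling	2	GNG7
Glutamate receptor signaling	2	CAMK4
Glutamate receptor signaling	2	SLC1A2
Glutamate receptor signaling	2	HOMER1
Glutamate receptor signaling	2	SLC1A7
Glutamate receptor signaling	2	GRIK1
Glutamate receptor signaling	2	GRIN2A
Glutamate receptor signaling	2	GRM4
Glutamate receptor signaling	2	GRIK4
Glutamate receptor signaling	2	SLC1A1
Glutamate receptor signaling	2	GRM7
Glutamate receptor signaling	2	GNG2
Glutamate receptor signaling	2	GRM5
Glutamate receptor signaling	2	GRM6
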