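pop_a	pop_b	pop_c	f3	se	z
AR	CH	SP	-0.00165	0.000171	-9.63768
AR	CR	SP	-0.00178	0.000171	-10.4413
AR	CN	SP	-0.00078	0.00015	-5.15567
AR	OV	SP	-0.00082	0.000145	-5.63104
AR	RO	SP	-0.00076	0.000151	-5.05319
AR	SE	SP	-0.00077	0.00014	-5.47246
LC	CH	SP	-0.00146	0.000193	-7.56011
LC	CR	SP	-0.00154	0.000211	-7.31075
LC	OV	SP	-0.00054	0.00018	-3.00356
RI	CH	SP	-0.00285	0.000948	-3.00128
RI	CR	SP	-0.00296	0.000965	-3.06668
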