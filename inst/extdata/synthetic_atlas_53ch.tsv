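channel	hemisphere	roi
1	left	FPA
2	left	FPA
3	left	FPA
4	left	FPA
5	left	FPA
6	left	DLPFC
7	left	DLPFC
8	left	DLPFC
9	left	DLPFC
10	left	DLPFC
11	left	FEF
12	left	FEF
13	left	FEF
14	left	FEF
15	left	FEF
16	left	BROCA
17	left	BROCA
18	left	BROCA
19	left	BROCA
20	left	BROCA
21	left	PreM_SMA
22	left	PreM_SMA
23	left	PreM_SMA
24	left	PreM_SMA
25	midline	FPA
26	left	PreM_SMA
27	right	FPA
28	midline	FPA
29	midline	FPA
30	right	FPA
31	right	FPA
32	right	FPA
33	right	FPA
34	right	DLPFC
35	right	DLPFC
36	right	DLPFC
37	right	DLPFC
38	right	DLPFC
39	right	FEF
40	right	FEF
41	right	FEF
42	right	FEF
43	right	FEF
44	right	BROCA
45	right	BROCA
46	right	BROCA
47	right	BROCA
48	right	BROCA
49	right	PreM_SMA
50	right	PreM_SMA
51	right	PreM_SMA
52	right	PreM_SMA
53	right	PreM_SMA
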