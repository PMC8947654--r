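label_id	parcel_name	composite	reference
1	lh_superior_frontal_1	frontal	0
2	lh_superior_frontal_2	frontal	0
3	lh_superior_frontal_3	frontal	0
4	rh_superior_frontal_1	frontal	0
5	rh_superior_frontal_2	frontal	0
6	rh_superior_frontal_3	frontal	0
7	lh_middle_frontal_1	frontal	0
8	lh_middle_frontal_2	frontal	0
9	rh_middle_frontal_1	frontal	0
10	rh_middle_frontal_2	frontal	0
11	lh_inferior_frontal_1	frontal	0
12	lh_inferior_frontal_2	frontal	0
13	rh_inferior_frontal_1	frontal	0
14	rh_inferior_frontal_2	frontal	0
15	lh_orbitofrontal_1	frontal	0
16	lh_orbitofrontal_2	frontal	0
17	rh_orbitofrontal_1	frontal	0
18	rh_orbitofrontal_2	frontal	0
19	lh_frontal_pole	frontal	0
20	rh_frontal_pole	frontal	0
21	lh_precentral	frontal	0
22	rh_precentral	frontal	0
23	lh_anterior_cingulate	anterior/posterior cingulate	0
24	rh_anterior_cingulate	anterior/posterior cingulate	0
25	lh_posterior_cingulate	anterior/posterior cingulate	0
26	rh_posterior_cingulate	anterior/posterior cingulate	0
27	lh_isthmus_cingulate	anterior/posterior cingulate	0
28	rh_isthmus_cingulate	anterior/posterior cingulate	0
29	lh_precuneus	anterior/posterior cingulate	0
30	rh_precuneus	anterior/posterior cingulate	0
31	lh_superior_parietal_1	lateral parietal	0
32	lh_superior_parietal_2	lateral parietal	0
33	rh_superior_parietal_1	lateral parietal	0
34	rh_superior_parietal_2	lateral parietal	0
35	lh_inferior_parietal_1	lateral parietal	0
36	lh_inferior_parietal_2	lateral parietal	0
37	rh_inferior_parietal_1	lateral parietal	0
38	rh_inferior_parietal_2	lateral parietal	0
39	lh_supramarginal	lateral parietal	0
40	rh_supramarginal	lateral parietal	0
41	lh_angular	lateral parietal	0
42	rh_angular	lateral parietal	0
43	lh_superior_temporal_1	lateral temporal	0
44	lh_superior_temporal_2	lateral temporal	0
45	rh_superior_temporal_1	lateral temporal	0
46	rh_superior_temporal_2	lateral temporal	0
47	lh_middle_temporal_1	lateral temporal	0
48	lh_middle_temporal_2	lateral temporal	0
49	rh_middle_temporal_1	lateral temporal	0
50	rh_middle_temporal_2	lateral temporal	0
51	lh_inferior_temporal	lateral temporal	0
52	rh_inferior_temporal	lateral temporal	0
53	lh_temporal_pole	lateral temporal	0
54	rh_temporal_pole	lateral temporal	0
55	lh_caudate	striatum	0
56	rh_caudate	striatum	0
57	lh_putamen	striatum	0
58	rh_putamen	striatum	0
59	lh_nucleus_accumbens	striatum	0
60	rh_nucleus_accumbens	striatum	0
61	lh_occipital		0
62	rh_occipital		0
63	lh_lingual		0
64	rh_lingual		0
65	lh_cuneus		0
66	rh_cuneus		0
67	lh_pericalcarine		0
68	rh_pericalcarine		0
69	lh_parahippocampal		0
70	rh_parahippocampal		0
71	lh_entorhinal		0
72	rh_entorhinal		0
73	lh_fusiform		0
74	rh_fusiform		0
75	lh_insula		0
76	rh_insula		0
77	lh_hippocampus		0
78	rh_hippocampus		0
79	lh_amygdala		0
80	rh_amygdala		0
81	lh_thalamus		0
82	rh_thalamus		0
83	lh_pallidum		0
84	rh_pallidum		0
85	lh_cerebral_white_matter		0
86	rh_cerebral_white_matter		0
87	lh_cerebellum_cortex		0
88	rh_cerebellum_cortex		0
89	lh_cerebellum_white_matter		0
90	rh_cerebellum_white_matter		0
91	lh_ventricle		0
92	rh_ventricle		0
93	brainstem_midbrain		0
94	brainstem_medulla		0
95	lh_paracentral		0
96	rh_paracentral		0
97	csf		0
98	pons		1
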