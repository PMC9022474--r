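region	label	x	y	z
1	Precentral_L	-39	-6	51
2	Precentral_R	39	-6	51
3	Frontal_Sup_L	-18	35	42
4	Frontal_Sup_R	18	35	42
5	Frontal_Sup_Orb_L	-17	47	-13
6	Frontal_Sup_Orb_R	17	47	-13
7	Frontal_Mid_L	-34	33	35
8	Frontal_Mid_R	34	33	35
9	Frontal_Mid_Orb_L	-31	50	-10
10	Frontal_Mid_Orb_R	31	50	-10
11	Frontal_Inf_Oper_L	-48	13	19
12	Frontal_Inf_Oper_R	48	13	19
13	Frontal_Inf_Tri_L	-46	30	14
14	Frontal_Inf_Tri_R	46	30	14
15	Frontal_Inf_Orb_L	-36	31	-12
16	Frontal_Inf_Orb_R	36	31	-12
17	Rolandic_Oper_L	-47	-8	14
18	Rolandic_Oper_R	47	-8	14
19	Supp_Motor_Area_L	-6	5	61
20	Supp_Motor_Area_R	6	5	61
21	Olfactory_L	-8	15	-11
22	Olfactory_R	8	15	-11
23	Frontal_Sup_Medial_L	-5	49	31
24	Frontal_Sup_Medial_R	5	49	31
25	Frontal_Med_Orb_L	-5	54	-7
26	Frontal_Med_Orb_R	5	54	-7
27	Rectus_L	-5	37	-18
28	Rectus_R	5	37	-18
29	Insula_L	-35	7	3
30	Insula_R	35	7	3
31	Cingulum_Ant_L	-4	35	14
32	Cingulum_Ant_R	4	35	14
33	Cingulum_Mid_L	-5	-15	42
34	Cingulum_Mid_R	5	-15	42
35	Cingulum_Post_L	-5	-43	25
36	Cingulum_Post_R	5	-43	25
37	Hippocampus_L	-25	-21	-10
38	Hippocampus_R	25	-21	-10
39	ParaHippocampal_L	-21	-16	-21
40	ParaHippocampal_R	21	-16	-21
41	Amygdala_L	-23	-1	-17
42	Amygdala_R	23	-1	-17
43	Calcarine_L	-7	-79	6
44	Calcarine_R	7	-79	6
45	Cuneus_L	-6	-80	27
46	Cuneus_R	6	-80	27
47	Lingual_L	-15	-68	-5
48	Lingual_R	15	-68	-5
49	Occipital_Sup_L	-17	-84	28
50	Occipital_Sup_R	17	-84	28
51	Occipital_Mid_L	-32	-81	16
52	Occipital_Mid_R	32	-81	16
53	Occipital_Inf_L	-36	-78	-8
54	Occipital_Inf_R	36	-78	-8
55	Fusiform_L	-31	-40	-20
56	Fusiform_R	31	-40	-20
57	Postcentral_L	-42	-23	49
58	Postcentral_R	42	-23	49
59	Parietal_Sup_L	-23	-60	59
60	Parietal_Sup_R	23	-60	59
61	Parietal_Inf_L	-43	-46	47
62	Parietal_Inf_R	43	-46	47
63	SupraMarginal_L	-56	-34	30
64	SupraMarginal_R	56	-34	30
65	Angular_L	-44	-61	36
66	Angular_R	44	-61	36
67	Precuneus_L	-7	-56	48
68	Precuneus_R	7	-56	48
69	Paracentral_Lobule_L	-8	-25	70
70	Paracentral_Lobule_R	8	-25	70
71	Caudate_L	-11	11	9
72	Caudate_R	11	11	9
73	Putamen_L	-24	4	2
74	Putamen_R	24	4	2
75	Pallidum_L	-18	0	0
76	Pallidum_R	18	0	0
77	Thalamus_L	-11	-18	8
78	Thalamus_R	11	-18	8
79	Heschl_L	-42	-19	10
80	Heschl_R	42	-19	10
81	Temporal_Sup_L	-53	-21	7
82	Temporal_Sup_R	53	-21	7
83	Temporal_Pole_Sup_L	-40	15	-20
84	Temporal_Pole_Sup_R	40	15	-20
85	Temporal_Mid_L	-56	-34	-2
86	Temporal_Mid_R	56	-34	-2
87	Temporal_Pole_Mid_L	-36	15	-34
88	Temporal_Pole_Mid_R	36	15	-34
89	Temporal_Inf_L	-50	-28	-23
90	Temporal_Inf_R	50	-28	-23
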