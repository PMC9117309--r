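roi_id	name	rsn	x	y	z
1	LH_Vis_1	Vis	-47	-80	62
2	LH_Vis_2	Vis	-38	37	32
3	LH_Vis_3	Vis	-13	-31	-4
4	LH_Vis_4	Vis	-22	-86	71
5	LH_Vis_5	Vis	-38	-71	7
6	LH_Vis_6	Vis	-7	-70	46
7	LH_Vis_7	Vis	-33	11	-25
8	LH_Vis_8	Vis	-57	0	71
9	LH_Vis_9	Vis	-20	-57	57
10	LH_Vis_10	Vis	-40	-3	26
11	LH_Vis_11	Vis	-5	-33	42
12	LH_Vis_12	Vis	-47	43	-23
13	LH_Vis_13	Vis	-19	-82	-33
14	LH_Vis_14	Vis	-56	-47	-31
15	LH_Vis_15	Vis	-14	-72	67
16	LH_Vis_16	Vis	-26	-91	24
17	LH_SomMot_1	SomMot	-38	-9	-26
18	LH_SomMot_2	SomMot	-5	-77	-24
19	LH_SomMot_3	SomMot	-24	-74	-23
20	LH_SomMot_4	SomMot	-6	29	0
21	LH_SomMot_5	SomMot	-25	-27	-32
22	LH_SomMot_6	SomMot	-26	-78	32
23	LH_SomMot_7	SomMot	-19	-7	-27
24	LH_SomMot_8	SomMot	-9	28	45
25	LH_SomMot_9	SomMot	-30	-30	2
26	LH_SomMot_10	SomMot	-16	-90	60
27	LH_SomMot_11	SomMot	-30	-36	41
28	LH_SomMot_12	SomMot	-13	-24	-25
29	LH_SomMot_13	SomMot	-5	-93	-13
30	LH_SomMot_14	SomMot	-41	-32	-19
31	LH_SomMot_15	SomMot	-60	-35	8
32	LH_SomMot_16	SomMot	-16	6	-17
33	LH_SomMot_17	SomMot	-49	-94	5
34	LH_DorsAttn_1	DorsAttn	-6	-85	17
35	LH_DorsAttn_2	DorsAttn	-40	44	61
36	LH_DorsAttn_3	DorsAttn	-31	-99	43
37	LH_DorsAttn_4	DorsAttn	-18	-74	74
38	LH_DorsAttn_5	DorsAttn	-34	-16	-32
39	LH_DorsAttn_6	DorsAttn	-50	-8	-24
40	LH_DorsAttn_7	DorsAttn	-32	-44	63
41	LH_DorsAttn_8	DorsAttn	-27	15	72
42	LH_DorsAttn_9	DorsAttn	-57	-53	22
43	LH_DorsAttn_10	DorsAttn	-31	-17	73
44	LH_DorsAttn_11	DorsAttn	-31	6	54
45	LH_DorsAttn_12	DorsAttn	-10	50	28
46	LH_DorsAttn_13	DorsAttn	-7	-88	20
47	LH_SalVentAttn_1	SalVentAttn	-61	-67	54
48	LH_SalVentAttn_2	SalVentAttn	-23	5	-4
49	LH_SalVentAttn_3	SalVentAttn	-36	11	-35
50	LH_SalVentAttn_4	SalVentAttn	-19	-91	-31
51	LH_SalVentAttn_5	SalVentAttn	-63	-73	38
52	LH_SalVentAttn_6	SalVentAttn	-43	-92	2
53	LH_SalVentAttn_7	SalVentAttn	-62	62	-6
54	LH_SalVentAttn_8	SalVentAttn	-58	-12	41
55	LH_SalVentAttn_9	SalVentAttn	-36	24	10
56	LH_SalVentAttn_10	SalVentAttn	-48	22	-20
57	LH_SalVentAttn_11	SalVentAttn	-49	-40	42
58	LH_SalVentAttn_12	SalVentAttn	-8	15	64
59	LH_Limbic_1	Limbic	-62	29	58
60	LH_Limbic_2	Limbic	-17	-96	34
61	LH_Limbic_3	Limbic	-23	-80	15
62	LH_Limbic_4	Limbic	-59	-17	28
63	LH_Limbic_5	Limbic	-39	54	75
64	LH_Limbic_6	Limbic	-32	-81	-11
65	LH_Cont_1	Cont	-29	-80	43
66	LH_Cont_2	Cont	-10	-38	-16
67	LH_Cont_3	Cont	-43	-90	8
68	LH_Cont_4	Cont	-33	-26	28
69	LH_Cont_5	Cont	-39	-21	37
70	LH_Cont_6	Cont	-45	-84	46
71	LH_Cont_7	Cont	-58	32	13
72	LH_Cont_8	Cont	-28	20	15
73	LH_Cont_9	Cont	-48	-18	-24
74	LH_Cont_10	Cont	-56	29	-14
75	LH_Cont_11	Cont	-16	-63	40
76	LH_Cont_12	Cont	-43	-6	28
77	LH_Cont_13	Cont	-48	45	55
78	LH_Default_1	Default	-38	55	41
79	LH_Default_2	Default	-17	64	35
80	LH_Default_3	Default	-59	-13	-37
81	LH_Default_4	Default	-12	-96	34
82	LH_Default_5	Default	-62	-55	48
83	LH_Default_6	Default	-52	53	25
84	LH_Default_7	Default	-63	4	35
85	LH_Default_8	Default	-12	-48	52
86	LH_Default_9	Default	-64	-57	21
87	LH_Default_10	Default	-42	38	-29
88	LH_Default_11	Default	-61	-76	-32
89	LH_Default_12	Default	-17	-94	61
90	LH_Default_13	Default	-18	-32	48
91	LH_Default_14	Default	-60	-34	-19
92	LH_Default_15	Default	-48	-84	62
93	LH_Default_16	Default	-51	-72	33
94	LH_Default_17	Default	-22	51	60
95	LH_Default_18	Default	-26	-49	50
96	LH_Default_19	Default	-25	-50	34
97	LH_Default_20	Default	-52	-77	28
98	LH_Default_21	Default	-27	-9	18
99	LH_Default_22	Default	-45	6	-33
100	LH_Default_23	Default	-27	-68	10
101	RH_Vis_1	Vis	36	-45	4
102	RH_Vis_2	Vis	35	-33	40
103	RH_Vis_3	Vis	43	12	47
104	RH_Vis_4	Vis	26	-75	-20
105	RH_Vis_5	Vis	55	-32	0
106	RH_Vis_6	Vis	11	-86	-33
107	RH_Vis_7	Vis	46	-95	13
108	RH_Vis_8	Vis	22	-26	36
109	RH_Vis_9	Vis	48	-36	68
110	RH_Vis_10	Vis	54	24	28
111	RH_Vis_11	Vis	57	59	-10
112	RH_Vis_12	Vis	50	-19	19
113	RH_Vis_13	Vis	19	-46	7
114	RH_Vis_14	Vis	52	10	13
115	RH_Vis_15	Vis	21	-54	67
116	RH_Vis_16	Vis	55	-64	-5
117	RH_SomMot_1	SomMot	35	-25	2
118	RH_SomMot_2	SomMot	32	-54	52
119	RH_SomMot_3	SomMot	43	57	-7
120	RH_SomMot_4	SomMot	42	-36	27
121	RH_SomMot_5	SomMot	60	-68	29
122	RH_SomMot_6	SomMot	32	-91	74
123	RH_SomMot_7	SomMot	17	29	44
124	RH_SomMot_8	SomMot	62	-30	50
125	RH_SomMot_9	SomMot	16	-56	-10
126	RH_SomMot_10	SomMot	46	-52	45
127	RH_SomMot_11	SomMot	52	-39	11
128	RH_SomMot_12	SomMot	43	-40	-10
129	RH_SomMot_13	SomMot	26	-40	12
130	RH_SomMot_14	SomMot	50	28	10
131	RH_SomMot_15	SomMot	30	29	-21
132	RH_SomMot_16	SomMot	47	-41	-12
133	RH_SomMot_17	SomMot	49	20	18
134	RH_DorsAttn_1	DorsAttn	57	-46	-32
135	RH_DorsAttn_2	DorsAttn	21	42	70
136	RH_DorsAttn_3	DorsAttn	56	-24	-21
137	RH_DorsAttn_4	DorsAttn	19	41	53
138	RH_DorsAttn_5	DorsAttn	37	-36	4
139	RH_DorsAttn_6	DorsAttn	29	62	-13
140	RH_DorsAttn_7	DorsAttn	42	-56	-22
141	RH_DorsAttn_8	DorsAttn	26	-13	33
142	RH_DorsAttn_9	DorsAttn	38	-52	49
143	RH_DorsAttn_10	DorsAttn	20	-99	6
144	RH_DorsAttn_11	DorsAttn	11	-66	56
145	RH_DorsAttn_12	DorsAttn	54	-51	10
146	RH_DorsAttn_13	DorsAttn	9	5	-12
147	RH_SalVentAttn_1	SalVentAttn	24	-64	53
148	RH_SalVentAttn_2	SalVentAttn	23	-8	-7
149	RH_SalVentAttn_3	SalVentAttn	37	-37	44
150	RH_SalVentAttn_4	SalVentAttn	23	-96	-35
151	RH_SalVentAttn_5	SalVentAttn	38	44	55
152	RH_SalVentAttn_6	SalVentAttn	64	-13	-27
153	RH_SalVentAttn_7	SalVentAttn	7	-53	38
154	RH_SalVentAttn_8	SalVentAttn	8	17	-36
155	RH_SalVentAttn_9	SalVentAttn	43	-65	-16
156	RH_SalVentAttn_10	SalVentAttn	59	-24	2
157	RH_SalVentAttn_11	SalVentAttn	61	14	-4
158	RH_SalVentAttn_12	SalVentAttn	8	18	64
159	RH_Limbic_1	Limbic	35	25	-27
160	RH_Limbic_2	Limbic	50	37	-4
161	RH_Limbic_3	Limbic	18	-33	44
162	RH_Limbic_4	Limbic	21	41	53
163	RH_Limbic_5	Limbic	59	9	65
164	RH_Limbic_6	Limbic	15	-95	5
165	RH_Cont_1	Cont	41	14	-34
166	RH_Cont_2	Cont	18	-28	5
167	RH_Cont_3	Cont	56	6	21
168	RH_Cont_4	Cont	61	-70	29
169	RH_Cont_5	Cont	40	-53	40
170	RH_Cont_6	Cont	60	-13	-36
171	RH_Cont_7	Cont	49	27	8
172	RH_Cont_8	Cont	38	-36	45
173	RH_Cont_9	Cont	61	-98	-16
174	RH_Cont_10	Cont	35	-42	-33
175	RH_Cont_11	Cont	50	21	-22
176	RH_Cont_12	Cont	13	46	-30
177	RH_Cont_13	Cont	44	8	64
178	RH_Default_1	Default	10	-94	17
179	RH_Default_2	Default	20	62	8
180	RH_Default_3	Default	17	31	31
181	RH_Default_4	Default	48	0	61
182	RH_Default_5	Default	59	-15	36
183	RH_Default_6	Default	25	-10	-10
184	RH_Default_7	Default	37	-28	-21
185	RH_Default_8	Default	64	46	64
186	RH_Default_9	Default	46	44	-35
187	RH_Default_10	Default	43	27	41
188	RH_Default_11	Default	19	-5	47
189	RH_Default_12	Default	18	-18	19
190	RH_Default_13	Default	36	20	19
191	RH_Default_14	Default	62	-19	61
192	RH_Default_15	Default	51	-1	-8
193	RH_Default_16	Default	24	-8	1
194	RH_Default_17	Default	7	20	5
195	RH_Default_18	Default	8	-77	1
196	RH_Default_19	Default	45	-45	-32
197	RH_Default_20	Default	14	47	17
198	RH_Default_21	Default	53	48	73
199	RH_Default_22	Default	36	-51	13
200	RH_Default_23	Default	6	51	68
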