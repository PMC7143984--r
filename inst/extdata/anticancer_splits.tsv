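id	split1	split2	split3
1	training	training	training
2	validation	validation	training
3	validation	validation	validation
4	training	validation	training
5	validation	training	training
6	training	training	training
7	training	training	training
8	training	training	training
9	training	training	training
10	validation	training	training
11	validation	training	training
12	training	training	training
13	training	training	training
14	training	training	training
15	training	training	training
16	training	training	training
17	training	validation	training
18	training	training	training
19	training	training	training
20	training	validation	validation
21	training	validation	training
22	validation	training	validation
23	training	training	training
25	training	training	training
26	validation	training	training
27	training	training	training
29	training	validation	training
30	training	validation	validation
31	training	training	training
32	validation	training	training
33	training	training	validation
34	training	training	validation
35	validation	validation	training
36	training	training	training
37	training	validation	training
38	training	validation	training
39	validation	training	training
40	training	training	training
41	training	training	training
42	training	training	training
43	validation	training	training
45	training	training	training
46	training	training	validation
47	validation	training	training
48	training	training	training
51	training	training	training
52	training	validation	validation
54	training	training	training
55	training	training	validation
56	training	training	training
57	training	training	training
59	training	training	training
60	training	validation	training
61	training	training	validation
63	training	training	validation
64	training	validation	training
65	training	training	training
67	training	training	validation
68	validation	training	training
69	training	training	training
70	training	validation	training
71	validation	training	training
73	training	training	training
74	training	training	training
75	training	training	training
77	training	training	training
90	training	validation	validation
92	validation	training	validation
94	training	validation	training
98	training	training	training
99	training	validation	training
103	validation	training	validation
109	training	training	training
112	training	training	validation
116	training	training	training
117	training	training	validation
118	training	validation	training
120	training	validation	validation
121	training	training	training
122	training	validation	validation
123	training	training	validation
124	training	training	training
125	validation	training	training
126	training	validation	validation
130	training	training	training
136	training	training	training
143	validation	training	training
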