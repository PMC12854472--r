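anc_node	descendant	d2	net_mean	ggd_mean	cat_mean	net_lower	ggd_lower	cat_lower	net_upper	ggd_upper	cat_upper
1	Pan_troglodytes_troglodytes	14.47	1.11	16.06	slow	0.61	8.83	slow	1.62	23.44	slow
1	Pan_troglodytes_schweinfurthii	13.88	1.11	15.40	slow	0.61	8.47	slow	1.62	22.48	slow
2	Pan_troglodytes_verus	46.77	0.37	17.31	slow	0.23	10.76	slow	0.50	23.39	slow
2	node1	8.73	0.37	3.23	slow	0.23	2.01	slow	0.50	4.36	slow
3	Pan_paniscus	150.91	0.27	40.75	neutral	0.18	27.16	slow	0.35	52.82	neutral
3	node2	13.63	0.27	3.68	slow	0.18	2.45	slow	0.35	4.77	slow
4	Homo_sapiens	669.03	0.18	120.43	fast	0.14	93.66	fast	0.23	153.88	fast
4	node3	173.06	0.18	31.15	slow	0.14	24.23	slow	0.21	36.34	neutral
5	Gorilla_beringei_beringei	113.07	0.69	78.02	fast	0.40	45.23	neutral	0.99	111.94	fast
5	Gorilla_beringei_graueri	23.57	0.69	16.26	slow	0.40	9.43	slow	0.99	23.33	slow
6	Gorilla_gorilla	74.78	0.26	19.44	slow	0.18	13.46	slow	0.33	24.68	slow
6	node5	43.71	0.26	11.37	slow	0.18	7.87	slow	0.33	14.43	slow
7	node6	164.44	0.15	24.67	slow	0.12	19.73	slow	0.18	29.60	slow
7	node4	12.92	0.15	1.94	slow	0.12	1.55	slow	0.18	2.33	slow
8	Pongo_pygmaeus	49.88	0.36	17.96	slow	0.23	11.47	slow	0.50	24.94	slow
8	Pongo_abelii	134.15	0.36	48.29	neutral	0.23	30.85	slow	0.50	67.08	fast
9	node7	89.87	0.15	13.48	slow	0.12	10.78	slow	0.18	16.18	slow
9	node8	208.54	0.15	31.28	slow	0.12	25.02	slow	0.18	37.54	neutral
10	Hylobates_muelleri	38.09	0.16	6.09	slow	0.13	4.95	slow	0.19	7.24	slow
10	Hylobates_agilis	35.67	0.16	5.71	slow	0.13	4.64	slow	0.19	6.78	slow
11	Hylobates_lar	34.13	0.14	4.78	slow	0.12	4.10	slow	0.17	5.80	slow
11	node10	6.18	0.14	0.87	slow	0.12	0.74	slow	0.17	1.05	slow
12	Symphalangus_syndactylus	65.41	0.23	15.04	slow	0.16	10.47	slow	0.29	18.97	slow
12	node11	113.92	0.23	26.20	slow	0.16	18.23	slow	0.29	33.04	neutral
13	Hoolock_hoolock	46.40	0.18	8.35	slow	0.14	6.50	slow	0.23	10.67	slow
13	node12	0.43	0.18	0.08	slow	0.14	0.06	slow	0.23	0.10	slow
14	node9	15.52	0.14	2.17	slow	0.12	1.86	slow	0.16	2.48	slow
14	node13	498.49	0.14	69.79	fast	0.12	59.82	neutral	0.16	79.76	fast
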