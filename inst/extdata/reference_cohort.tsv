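brain_area	sample_id	rna_iq	conc_ug_ul	group	ev	q0	omax	pmax	excluded
Hip	Hip 45	7	2.3208	METH	0.82	19.00	22.77	3.69	FALSE
Hip	Hip 46	7	2.4656	METH	0.79	2.80	22.06	24.28	FALSE
Hip	Hip 47	8.2	1.48624	METH	2.64	6.00	73.54	37.77	FALSE
Hip	Hip 48	7.6	1.95136	METH	1.81	7.20	50.43	21.58	FALSE
Hip	Hip 51	7.4	1.80288	METH	1.01	8.90	28.24	9.78	FALSE
Hip	Hip 52	9.1	0.85248	METH	4.22	5.10	117.66	71.10	FALSE
PFC	PFC 45	7.6	2.14736	METH	0.82	19.00	22.77	3.69	FALSE
PFC	PFC 46	7.2	2.6532	METH	0.79	2.80	22.06	24.28	FALSE
PFC	PFC 47	7.4	2.3032	METH	2.64	6.00	73.54	37.77	FALSE
PFC	PFC 48	8.3	1.44056	METH	1.81	7.20	50.43	21.58	FALSE
PFC	PFC 51	7.6	2.29496	METH	1.01	8.90	28.24	9.78	TRUE
PFC	PFC 52	7.6	3.15064	METH	4.22	5.10	117.66	71.10	FALSE
Hip	Hip 39	6.8	2.19064	SAL	0.09	0.87	2.61	9.26	FALSE
Hip	Hip 40	7.2	2.26464	SAL	0.00	0.74	0.11	0.46	FALSE
Hip	Hip 44	7.2	2.26144	SAL	0.13	1.40	3.53	7.77	FALSE
Hip	Hip 49	7.8	1.41472	SAL	0.15	2.30	4.15	5.56	FALSE
Hip	Hip 50	7.8	1.70512	SAL	0.19	1.70	5.43	9.84	FALSE
Hip	Hip 53	8.1	1.73056	SAL	0.07	0.52	1.91	11.31	FALSE
PFC	PFC 39	8	1.51104	SAL	0.09	0.87	2.61	9.26	FALSE
PFC	PFC 40	7.5	2.19352	SAL	0.00	0.74	0.11	0.46	FALSE
PFC	PFC 44	7.5	2.18944	SAL	0.13	1.40	3.53	7.77	FALSE
PFC	PFC 49	7.7	2.88296	SAL	0.15	2.30	4.15	5.56	FALSE
PFC	PFC 50	7.9	1.84504	SAL	0.19	1.70	5.43	9.84	FALSE
PFC	PFC 53	7.9	1.9628	SAL	0.07	0.52	1.91	11.31	FALSE
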