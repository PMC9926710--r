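gene	gastrozooid	female_gonozooid	male_gonozooid
HyS2624.1	2.43	211.27	1.89
HyS0007.282	0.87	31.75	1.14
HyS0069.11	2.60	26.69	1.83
HyS0918.1	4.10	15.36	4.17
HyS0148.2	3.15	10.27	2.70
HyS4472.1	1.91	5.44	0.04
HyS0067.50	1.91	5.21	0.58
HyS0067.52	2.85	5.66	1.03
HyS0007.322	3.09	8.03	4.23
HyS0007.412	2.83	0.40	943.95
HyS0057.61	2.08	0.00	859.64
HyS0057.48	2.84	0.04	531.51
HyS0057.36	4.26	0.27	475.83
HyS0070.65	1.93	0.05	376.95
HyS0007.262	2.50	3.75	194.30
HyS0057.16	3.91	3.05	32.44
HyS0070.25	3.27	1.73	31.05
HyS0113.24	4.63	0.06	12.41
HyS0057.114	2.15	0.21	11.43
HyS0007.257	1.64	0.98	11.43
HyS0120.42	2.88	0.35	9.24
HyS0007.368	3.36	0.24	8.58
HyS0067.49	0.80	2.18	10.50
HyS0070.83	3.02	0.23	8.50
HyS0067.65	1.39	0.27	7.65
HyS0007.261	1.67	0.20	7.50
HyS0057.88	2.81	0.19	6.35
HyS0070.60	4.87	2.62	7.85
HyS0244.4	3.75	1.98	6.79
HyS1699.2	4.16	2.40	5.84
HyS0007.387	2.71	3.01	5.09
HyS0070.70	4.29	3.84	5.76
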