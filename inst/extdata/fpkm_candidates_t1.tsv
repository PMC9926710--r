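gene	gastrozooid	female_gonozooid	male_gonozooid
HyS1036.2	0.15	22.62	0.47
HyS2624.2	0.00	12.47	0.00
HyS0007.332	0.00	9.66	0.00
HyS0116.3	0.00	5.77	0.00
HyS0070.121	0.00	2.19	0.30
HyS0120.5	0.00	1.64	0.00
HyS0328.2	0.00	1.05	0.00
HyS0070.32	0.51	1.03	0.14
HyS0007.350	0.36	1.35	0.87
HyS0070.46	0.34	0.11	358.41
HyS0057.51	0.84	0.03	314.84
HyS0057.46	1.00	0.00	192.60
HyS0007.291	0.27	0.15	115.53
HyS0057.47	0.00	0.00	67.81
HyS0067.10	0.16	0.00	30.26
HyS0070.23	0.45	0.00	27.85
HyS0070.81	0.07	0.00	18.79
HyS0113.16	0.76	0.00	6.41
HyS0067.3	0.45	0.03	5.67
HyS0113.15	0.00	0.00	4.61
HyS0067.73	0.00	0.00	4.37
HyS0069.15	0.50	0.52	4.75
HyS0007.328	0.27	0.24	3.76
HyS0057.18	0.00	0.00	3.30
HyS0067.71	0.59	0.00	2.85
HyS4443.1	0.37	0.16	2.20
HyS0057.124	0.00	0.09	1.81
HyS0057.129	0.31	0.12	1.82
HyS0069.70	0.00	0.00	1.64
HyS1036.1	0.03	0.31	1.82
HyS0070.5	0.14	0.00	1.45
HyS0116.7	0.93	0.91	2.20
HyS0069.45	0.00	0.00	1.19
HyS0057.71	0.67	0.06	1.20
HyS0067.4	0.06	0.00	1.07
HyS0007.327	0.00	0.00	1.02
HyS0070.97	0.97	0.17	1.07
HyS0057.113	0.44	0.51	1.27
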