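# SYNTHETIC stand-in for an inter-chain contact-strength table
# (Keskin et al. style). NOT the published Keskin values: this
# table is the MJ magnitude table scaled by 0.9, preserving the
# MJ rank ordering while mimicking weaker inter-chain contacts.
	C	M	F	I	L	V	W	Y	A	G	T	S	N	Q	D	E	H	R	K	P
C	4.90	4.49	5.22	4.95	5.25	4.46	4.46	3.74	3.21	2.84	2.80	2.57	2.33	2.56	2.17	2.04	3.24	2.31	1.75	2.76
M	4.49	4.91	5.90	5.42	5.77	4.79	5.00	4.42	3.55	3.05	3.16	2.73	2.66	2.97	2.31	2.60	3.58	2.81	2.23	3.11
F	5.22	5.90	6.53	6.16	6.55	5.66	5.54	5.09	4.33	3.72	3.85	3.62	3.38	3.69	3.13	3.20	4.29	3.58	3.02	3.83
I	4.95	5.42	6.16	5.89	6.34	5.44	5.20	4.73	4.12	3.40	3.63	3.17	2.92	3.30	2.85	2.94	3.73	3.27	2.71	3.38
L	5.25	5.77	6.55	6.34	6.63	5.83	5.53	5.10	4.42	3.74	3.91	3.53	3.37	3.64	3.06	3.23	4.09	3.63	3.03	3.78
V	4.46	4.79	5.66	5.44	5.83	4.97	4.66	4.16	3.64	3.04	3.11	2.74	2.55	2.76	2.23	2.40	3.22	2.76	2.24	2.99
W	4.46	5.00	5.54	5.20	5.53	4.66	4.55	4.19	3.44	3.08	2.90	2.69	2.76	2.80	2.56	2.69	3.58	3.07	2.42	3.36
Y	3.74	4.42	5.09	4.73	5.10	4.16	4.19	3.75	3.02	2.71	2.71	2.50	2.48	2.67	2.48	2.51	3.17	2.84	2.34	2.87
A	3.21	3.55	4.33	4.12	4.42	3.64	3.44	3.02	2.45	2.08	2.09	1.81	1.66	1.70	1.53	1.36	2.17	1.65	1.18	1.83
G	2.84	3.05	3.72	3.40	3.74	3.04	3.08	2.71	2.08	2.02	1.87	1.64	1.57	1.49	1.43	1.10	1.94	1.55	1.03	1.68
T	2.80	3.16	3.85	3.63	3.91	3.11	2.90	2.71	2.09	1.87	1.91	1.76	1.69	1.71	1.62	1.57	2.18	1.71	1.18	1.71
S	2.57	2.73	3.62	3.17	3.53	2.74	2.69	2.50	1.81	1.64	1.76	1.50	1.42	1.34	1.47	1.33	1.90	1.46	0.95	1.41
N	2.33	2.66	3.38	2.92	3.37	2.55	2.76	2.48	1.66	1.57	1.69	1.42	1.51	1.54	1.51	1.36	1.87	1.48	1.09	1.38
Q	2.56	2.97	3.69	3.30	3.64	2.76	2.80	2.67	1.70	1.49	1.71	1.34	1.54	1.39	1.31	1.28	1.78	1.62	1.16	1.56
D	2.17	2.31	3.13	2.85	3.06	2.23	2.56	2.48	1.53	1.43	1.62	1.47	1.51	1.31	1.09	0.92	2.09	2.06	1.51	1.20
E	2.04	2.60	3.20	2.94	3.23	2.40	2.69	2.51	1.36	1.10	1.57	1.33	1.36	1.28	0.92	0.82	1.94	2.04	1.62	1.13
H	3.24	3.58	4.29	3.73	4.09	3.22	3.58	3.17	2.17	1.94	2.18	1.90	1.87	1.78	2.09	1.94	2.74	1.94	1.22	2.02
R	2.31	2.81	3.58	3.27	3.63	2.76	3.07	2.84	1.65	1.55	1.71	1.46	1.48	1.62	2.06	2.04	1.94	1.40	0.53	1.53
K	1.75	2.23	3.02	2.71	3.03	2.24	2.42	2.34	1.18	1.03	1.18	0.95	1.09	1.16	1.51	1.62	1.22	0.53	0.11	0.87
P	2.76	3.11	3.83	3.38	3.78	2.99	3.36	2.87	1.83	1.68	1.71	1.41	1.38	1.56	1.20	1.13	2.02	1.53	0.87	1.57
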