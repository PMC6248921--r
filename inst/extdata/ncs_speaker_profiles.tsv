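facet	label	n_can	mean_can	sd_can	n_us	mean_us	sd_us
N1	Anxiety	191	1.87	0.92	195	3.10	1.24
N2	Angry Hostility	187	1.89	1.20	194	3.59	1.25
N3	Depression	188	1.86	1.22	195	2.98	1.20
N4	Self-Consciousness	189	1.87	1.02	193	2.79	1.18
N5	Impulsiveness	188	2.84	1.13	195	4.04	1.10
N6	Vulnerability	188	2.28	1.06	193	3.12	1.16
E1	Warmth	188	4.14	0.95	195	3.02	0.91
E2	Gregariousness	188	4.02	0.90	194	3.83	1.18
E3	Assertiveness	188	3.25	1.02	193	3.64	1.16
E4	Activity	189	4.12	0.81	194	3.46	1.02
E5	Excitement-Seeking	189	3.83	0.94	194	3.86	1.07
E6	Positive Emotions	189	4.20	0.81	193	3.19	0.97
O1	Fantasy	188	3.09	1.02	194	3.12	1.10
O2	Aesthetics	188	3.22	0.97	195	2.30	1.04
O3	Feelings	189	3.83	0.82	194	2.71	0.99
O4	Actions	189	3.24	0.97	193	3.14	1.07
O5	Ideas	186	3.60	0.88	195	2.65	1.05
O6	Values	187	3.51	0.88	194	3.52	1.05
A1	Trust	188	3.61	0.81	194	2.70	1.10
A2	Straightforwardness	188	3.84	0.82	195	2.87	1.13
A3	Altruism	189	3.90	0.83	194	2.43	0.91
A4	Compliance	188	3.27	1.06	194	2.20	0.97
A5	Modesty	187	3.59	1.01	195	2.17	0.90
A6	Tender-Mindedness	189	3.85	0.81	193	2.50	0.84
C1	Competence	188	3.88	0.74	193	2.34	1.00
C2	Order	188	3.53	0.85	194	2.16	0.91
C3	Dutifulness	188	3.66	0.87	194	2.28	0.87
C4	Achievement Striving	189	3.66	0.77	195	2.28	0.89
C5	Self-Discipline	189	3.65	0.81	195	2.56	1.01
C6	Deliberation	188	2.98	1.07	193	2.15	1.03
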