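facet	study_2b	study_2a
N1	0.86	1.23
N2	0.85	1.70
N3	0.71	1.12
N4	0.62	0.92
N5	0.37	1.20
N6	0.47	0.84
E1	-0.46	-1.12
E2	-0.15	-0.19
E3	0.06	0.39
E4	-0.34	-0.66
E5	-0.18	0.03
E6	-0.63	-1.01
O1	0.05	0.03
O2	-0.27	-0.93
O3	-0.04	-1.11
O4	0.10	-0.10
O5	-0.48	-0.95
O6	0.02	0.01
A1	-0.28	-0.91
A2	-0.53	-0.97
A3	-0.44	-1.48
A4	-0.31	-1.07
A5	-0.60	-1.42
A6	-0.56	-1.35
C1	-0.72	-1.55
C2	-0.57	-1.36
C3	-0.45	-1.38
C4	-0.45	-1.38
C5	-0.53	-1.09
C6	-0.28	-0.84
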