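facet	neo_pi_r	language_study_2a
N1	-0.25	1.01
N2	0.02	1.39
N3	-0.16	0.92
N4	-0.07	0.75
N5	0.03	0.97
N6	-0.11	0.69
E1	-0.11	-0.92
E2	-0.17	-0.16
E3	0.02	0.32
E4	0.11	-0.54
E5	0.14	0.02
E6	0.08	-0.83
O1	0.12	0.03
O2	-0.01	-0.75
O3	-0.09	-0.91
O4	-0.06	-0.08
O5	-0.05	-0.78
O6	-0.13	0.01
A1	0.12	-0.74
A2	0.39	-0.79
A3	0.04	-1.20
A4	0.18	-0.87
A5	0.10	-1.16
A6	0.17	-1.10
C1	0.01	-1.26
C2	-0.12	-1.11
C3	-0.12	-1.12
C4	-0.12	-1.12
C5	0.03	-0.89
C6	-0.20	-0.68
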