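pop	group	n_animals	lat	lon
ALS	1	30	48.57	7.75
BAR	1	59	45.47	-0.15
BOU	1	57	46.57	3.34
B11	1	60	46.21	5.23
B22	1	60	46.21	5.23
B55	1	43	46.21	5.23
CHA	1	56	46.44	4.28
CON	2	41	47.42	1.43
CNF	1	59	45.74	4.23
CDR	1	55	48.11	-1.68
GAS	1	60	43.43	0.58
GAT	1	57	48.15	2.70
GG	1	60	46.21	5.23
GN	1	58	46.63	5.22
GDT	1	59	47.13	1.00
GOU	1	58	49.48	1.72
GDV	1	44	45.02	5.29
HOU	1	58	48.79	1.60
HER	2	60	50.48	3.52
MAN	2	29	48.01	0.20
MAG	1	52	47.62	-1.19
MAR	2	65	46.30	-1.00
MER	1	38	48.70	0.29
NDB	1	56	46.95	1.99
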