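pop	breed	n_male_founders	n_female_founders	start_year	n_generations	n_sires_2013	n_dams_2013	mean_F_pct	ne_demo	ne_founders	delta_f_pct
ALS	Poule d'Alsace	20	33	2008	5	27	74	2.3	65	49.8	0.46
BAR	Barbezieux	7	7	2002	11	52	116	7.0	27	14	0.66
BOU	Bourbonnaise	75	232	2005	8	40	100	2.4	114	226.7	0.30
B22	Bresse Gauloise Blanche B22	26	102	2000	13	99	215	5.3	108	82.9	0.42
B11	Bresse Gauloise Blanche B11	23	256	1989	24	105	346	7.1	122	84.4	0.31
B55	Bresse Gauloise Blanche B55	23	255	1989	24	104	376	NA	153	84.4	NA
CHA	Charollaise	34	103	2005	8	20	43	2.7	63	102.3	0.34
CNF	Cou nu du Forez	34	98	2007	6	20	50	3.5	53	101	0.59
GAS	Gasconne	5	5	2009	4	24	77	7.2	22	10	1.85
GAT	Gatinaise	11	12	2006	7	40	112	5.6	56	23	0.82
GG	Gauloise Grise	77	252	1998	15	65	184	NA	285	235.9	NA
GN	Gauloise Noire	108	275	1996	17	20	83	5.3	119	310.2	0.32
GDT	Geline de Touraine	43	103	1996	17	55	110	4.2	142	121.3	0.25
GOU	Gournay	24	61	2003	10	46	104	NA	98	68.9	0.46
GDV	Grise du Vercors	29	83	2007	6	24	53	2.7	65	86	0.27
HOU	Houdan	30	81	2004	9	24	58	NA	80	87.6	NA
MER	Merlerault	18	32	2006	7	14	34	5.6	44	46.1	0.82
NDB	Noire du Berry	27	47	2008	5	47	103	2.7	99	68.6	0.55
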