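snp	chrom	pos	trait	beta	se	p
S01	1	10000	T1	0.50	0.10	0.01
S01	1	10000	T2	0.05	0.10	0.60
S01	1	10000	T3	-0.02	0.10	0.80
S01	1	10000	T4	0.01	0.10	0.90
S01	1	10000	T5	0.03	0.10	0.70
S02	1	20000	T1	0.10	0.10	0.30
S02	1	20000	T2	0.40	0.10	0.01
S02	1	20000	T3	-0.35	0.10	0.02
S02	1	20000	T4	0.30	0.10	0.03
S02	1	20000	T5	0.02	0.10	0.85
S03	1	30000	T1	0.60	0.10	0.001
S03	1	30000	T2	0.45	0.10	0.01
S03	1	30000	T3	0.25	0.10	0.04
S03	1	30000	T4	-0.05	0.10	0.65
S03	1	30000	T5	0.04	0.10	0.75
S04	1	40000	T1	0.15	0.10	0.20
S04	1	40000	T2	0.42	0.10	0.01
S04	1	40000	T3	0.41	0.10	0.01
S04	1	40000	T4	0.39	0.10	0.01
S04	1	40000	T5	-0.38	0.10	0.01
S05	1	50000	T1	0.55	0.10	0.002
S05	1	50000	T2	0.28	0.10	0.03
S05	1	50000	T3	0.06	0.10	0.55
S05	1	50000	T4	0.02	0.10	0.88
S05	1	50000	T5	-0.01	0.10	0.95
S06	1	60000	T1	0.25	0.10	0.05
S06	1	60000	T2	0.05	0.10	0.60
S06	1	60000	T3	0.03	0.10	0.77
S06	1	60000	T4	0.02	0.10	0.83
S06	1	60000	T5	0.01	0.10	0.92
S07	1	70000	T1	0.00	0.10	1.0
S07	1	70000	T2	0.00	0.10	1.0
S07	1	70000	T3	0.00	0.10	1.0
S07	1	70000	T4	0.00	0.10	1.0
S07	1	70000	T5	0.00	0.10	1.0
S08	1	80000	T1	0.12	0.10	0.25
S08	1	80000	T2	0.26	0.10	0.04
S08	1	80000	T3	0.27	0.10	0.04
S08	1	80000	T4	0.05	0.10	0.62
S08	1	80000	T5	0.04	0.10	0.71
S09	1	90000	T1	0.30	0.10	0.03
S09	1	90000	T2	0.70	0.10	0.001
S09	1	90000	T3	0.68	0.10	0.001
S09	1	90000	T4	-0.66	0.10	0.001
S09	1	90000	T5	0.65	0.10	0.001
S10	1	100000	T1	0.08	0.10	0.45
S10	1	100000	T2	0.06	0.10	0.58
S10	1	100000	T3	0.04	0.10	0.69
S10	1	100000	T4	0.03	0.10	0.79
S10	1	100000	T5	0.44	0.10	0.01
S11	2	10000	T1	0.27	0.10	0.04
S11	2	10000	T2	0.05	0.10	0.63
S11	2	10000	T3	0.04	0.10	0.72
S11	2	10000	T4	0.02	0.10	0.86
S11	2	10000	T5	0.01	0.10	0.94
S12	1	200000	T1	0.48	0.10	0.01
S12	1	200000	T2	0.47	0.10	0.01
S12	1	200000	T3	0.46	0.10	0.01
S12	1	200000	T4	0.06	0.10	0.57
S12	1	200000	T5	0.05	0.10	0.66
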