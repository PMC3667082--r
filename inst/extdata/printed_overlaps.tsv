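table	pair	side_a	side_b	n_background	n_a	n_b	overlap	expected_printed	p_printed
table1	EMT_up-GBM_up	up	up	11296	78	1386	34	9.57	4.53e-12
table1	EMT_down-GBM_down	down	down	11296	129	981	22	11.20	2.27e-3
table1	EMT_up-GBM_down	up	down	11296	78	981	8	6.77	5.47e-1
table1	EMT_down-GBM_up	down	up	11296	129	1386	8	15.83	3.07e-2
table3	EMT_up-Mes_up	up	up	11296	78	1610	40	11.12	9.65e-15
table3	EMT_up-Classical_up	up	up	11296	78	1456	34	10.05	1.83e-11
table3	EMT_up-Neural_up	up	up	11296	78	1174	29	8.11	2.99e-10
table3	EMT_up-Proneural_up	up	up	11296	78	1417	29	9.78	2.38e-8
table3	EMT_down-Mes_down	down	down	11296	129	1098	21	12.54	1.62e-2
table3	EMT_down-Classical_down	down	down	11296	129	1040	24	11.88	9.98e-4
table3	EMT_down-Neural_down	down	down	11296	129	837	17	9.56	1.73e-2
table3	EMT_down-Proneural_down	down	down	11296	129	951	23	10.86	5.79e-4
table3	EMT_down-Mes_up	down	up	11296	129	1610	14	18.39	3.11e-1
table3	EMT_down-Classical_up	down	up	11296	129	1456	7	16.63	7.80e-3
table3	EMT_down-Neural_up	down	up	11296	129	1174	7	13.41	7.93e-2
table3	EMT_down-Proneural_up	down	up	11296	129	1417	2	16.18	1.11e-5
table3	EMT_up-Mes_down	up	down	11296	78	1098	7	7.58	1.00
table3	EMT_up-Classical_down	up	down	11296	78	1040	8	7.18	6.94e-1
table3	EMT_up-Neural_down	up	down	11296	78	837	7	5.78	5.17e-1
table3	EMT_up-Proneural_down	up	down	11296	78	951	10	6.57	1.53e-1
table4	EMT_down-BT1pos_up	down	up	11774	132	486	14	5.4486	1.1e-3
table4	EMT_down-BT2pos_up	down	up	11774	132	377	15	4.2266	2.05e-5
table4	EMT_down-N1pos_up	down	up	11774	132	480	25	5.3813	9.93e-11
table4	EMT_down-N2pos_up	down	up	11774	132	836	64	9.3725	1.110e-38
table4	EMT_up-BT1pos_down	up	down	11774	77	191	1	1.2491	1.00
table4	EMT_up-BT2pos_down	up	down	11774	77	50	1	0.3270	2.80e-1
table4	EMT_up-N1pos_down	up	down	11774	77	77	1	0.5036	3.98e-1
table4	EMT_up-N2pos_down	up	down	11774	77	267	14	1.7461	1.59e-9
table5	Mes_up-BT1_up	up	up	11632	1659	486	208	69.32	1.38e-55
table5	Mes_up-BT2_up	up	up	11632	1659	382	177	54.48	2.72e-53
table5	Classical_up-BT1_up	up	up	11632	1511	486	139	63.13	1.17e-20
table5	Classical_up-BT2_up	up	up	11632	1511	382	67	49.62	1.04e-2
table5	Neural_up-BT1_up	up	up	11632	1212	486	147	50.64	3.54e-35
table5	Neural_up-BT2_up	up	up	11632	1212	382	116	39.80	5.97e-28
table5	Proneural_up-BT1_up	up	up	11632	1463	486	126	61.13	3.37e-16
table5	Proneural_up-BT2_up	up	up	11632	1463	382	57	48.05	1.58e-1
table5	Mes_down-BT1_down	down	down	11632	1128	184	68	17.84	8.28e-24
table5	Mes_down-BT2_down	down	down	11632	1128	47	5	4.56	8.03e-1
table5	Classical_down-BT1_down	down	down	11632	1059	184	65	16.75	4.53e-23
table5	Classical_down-BT2_down	down	down	11632	1059	47	5	4.28	6.14e-1
table5	Neural_down-BT1_down	down	down	11632	850	184	56	13.45	4.37e-21
table5	Neural_down-BT2_down	down	down	11632	850	47	2	3.43	5.80e-1
table5	Proneural_down-BT1_down	down	down	11632	963	184	57	15.23	3.02e-19
table5	Proneural_down-BT2_down	down	down	11632	963	47	4	3.89	7.94e-1
table5	Mes_down-BT1_up	down	up	11632	1128	486	19	47.13	1.44e-6
table5	Mes_down-BT2_up	down	up	11632	1128	382	17	37.04	1.46e-4
table5	Classical_down-BT1_up	down	up	11632	1059	486	26	44.25	2.15e-3
table5	Classical_down-BT2_up	down	up	11632	1059	382	31	34.78	5.87e-1
table5	Neural_down-BT1_up	down	up	11632	850	486	12	35.51	2.97e-6
table5	Neural_down-BT2_up	down	up	11632	850	382	16	27.91	1.59e-2
table5	Proneural_down-BT1_up	down	up	11632	963	486	24	40.24	5.32e-3
table5	Proneural_down-BT2_up	down	up	11632	963	382	28	31.63	5.71e-1
table5	Mes_up-BT1_down	up	down	11632	1659	184	12	26.24	1.35e-3
table5	Mes_up-BT2_down	up	down	11632	1659	47	10	6.70	2.05e-1
table5	Classical_up-BT1_down	up	down	11632	1511	184	11	23.90	2.68e-3
table5	Classical_up-BT2_down	up	down	11632	1511	47	5	6.11	8.28e-1
table5	Neural_up-BT1_down	up	down	11632	1212	184	12	19.17	8.81e-2
table5	Neural_up-BT2_down	up	down	11632	1212	47	5	4.90	1.00
table5	Proneural_up-BT1_down	up	down	11632	1463	184	11	23.14	4.78e-3
table5	Proneural_up-BT2_down	up	down	11632	1463	47	4	5.91	5.12e-1
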