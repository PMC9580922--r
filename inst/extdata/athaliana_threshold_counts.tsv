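# Reference HSD threshold-grid statistics for the Arabidopsis thaliana
# proteome (all-vs-all BLASTP, E-value <= 1e-5), used to validate the
# capturing-value and performance-score statistics at genome scale.
# groups_2/3/4plus are counts of HSD groups with 2 / 3 / >=4 gene copies.
identity_min	length_diff_max	candidate	true_count	space	incomplete	capturing_value	score	groups_2	groups_3	groups_4plus
60	10	8647	8245	1584	402	95	37	5064	1766	1817
60	30	9447	8797	1831	650	93	25	4888	1996	2563
60	50	9571	8767	1917	804	91	20	4626	2032	2913
60	70	9510	8610	1931	900	90	17	4416	1997	3097
60	100	9472	8434	1921	1038	89	15	4200	2016	3256
70	10	8440	8161	1525	279	96	53	5251	1665	1524
70	30	9566	9066	1772	500	94	33	5360	1986	2220
70	50	9912	9248	1873	664	93	25	5239	2082	2591
70	70	10030	9254	1896	776	92	22	5150	2081	2799
70	100	10125	9188	1898	937	90	18	4981	2155	2989
80	10	7970	7787	1427	183	97	77	5171	1570	1229
80	30	9316	8952	1699	364	96	45	5587	1920	1809
80	50	9841	9327	1803	514	94	33	5596	2081	2164
80	70	10095	9458	1840	637	93	27	5545	2138	2412
80	100	10337	9519	1852	818	92	21	5472	2244	2621
90	10	7404	7294	1371	110	98	120	4958	1451	995
90	30	8878	8599	1629	279	96	56	5586	1822	1470
90	50	9502	9080	1728	422	95	39	5722	1993	1787
90	70	9845	9294	1768	551	94	31	5745	2084	2016
90	100	10174	9448	1786	726	92	24	5738	2190	2246
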