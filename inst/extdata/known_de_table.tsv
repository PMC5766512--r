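mirna	cy_tpm	yk_tpm	fold_change	p_value	fdr	direction	n_targets
bta-miR-1247-5p	38.50574	9.358916	4.114338	2.10E-05	0.000101763	UP	2144
bta-miR-19b	1443.226	653.6905	2.207813	3.80E-71	7.16E-70	UP	86
bta-miR-2332	390.6089	150.3797	2.597485	1.47E-26	1.70E-25	UP	90
bta-miR-2411-3p	415.0229	158.272	2.622213	1.49E-28	1.81E-27	UP	858
bta-miR-2484	436.1548	131.3981	3.319338	2.15E-40	2.96E-39	UP	123
bta-miR-2904	443.8361	195.653	2.268486	3.96E-24	4.38E-23	UP	2963
bta-miR-369-3p	61.74624	25.47694	2.423613	0.000100687	0.00046171	UP	3
bta-miR-455-3p	64.47041	29.88945	2.156962	0.000283982	0.001267956	UP	1440
bta-miR-503-3p	150.1078	73.72338	2.036095	1.50E-07	9.09E-07	UP	195
bta-miR-574	151.2986	58.5845	2.582571	4.62E-11	3.41E-10	UP	1096
bta-miR-592	40.5238	3.391165	11.94982	4.01E-09	2.76E-08	UP	32
bta-miR-105a	2.976893	15.04598	0.197853	0.004449884	0.017558069	DOWN	443
bta-miR-10a	3470.423	7410.491	0.468312	1.02E-306	5.76E-305	DOWN	520
bta-miR-126-3p	1074.771	2427.455	0.442756	6.12E-114	1.56E-112	DOWN	35
bta-miR-126-5p	3907.057	7828.106	0.499106	6.83E-280	2.90E-278	DOWN	3
bta-miR-128	107.0503	262.7056	0.407491	1.26E-15	1.19E-14	DOWN	1349
bta-miR-130b	34.10613	80.56888	0.423316	2.51E-05	0.000119293	DOWN	274
bta-miR-133a	29.28078	116.9537	0.250362	4.82E-13	4.15E-12	DOWN	795
bta-miR-135a	54.15177	171.6531	0.315472	6.16E-15	5.60E-14	DOWN	303
bta-miR-139	24.77737	59.1521	0.418875	0.000194892	0.000877875	DOWN	418
bta-miR-143	34501.89	72492.95	0.475934	0	0	DOWN	697
bta-miR-146a	384.0079	1180.822	0.325204	2.41E-91	5.11E-90	DOWN	571
bta-miR-146b	9652.898	40429.24	0.23876	0	0	DOWN	727
bta-miR-147	1.883053	24.12422	0.078057	5.75E-06	2.93E-05	DOWN	647
bta-miR-15b	70.6145	282.1996	0.250229	1.82E-30	2.38E-29	DOWN	1677
bta-miR-16a	710.3616	1479.466	0.480147	3.90E-59	6.85E-58	DOWN	1534
bta-miR-16b	1600.679	4393.994	0.364288	7.94E-287	4.04E-285	DOWN	1138
bta-miR-184	0.508842	12.3765	0.041114	0.001839606	0.007675078	DOWN	811
bta-miR-18a	17.02364	67.22797	0.253223	5.76E-08	3.57E-07	DOWN	338
bta-miR-196a	6.022989	34.96246	0.17227	1.55E-05	7.66E-05	DOWN	607
bta-miR-2318	2.654966	25.76386	0.10305	1.55E-05	7.59E-05	DOWN	29
bta-miR-2419-5p	38.44689	76.92026	0.499828	0.000561739	0.002423095	DOWN	93
bta-miR-2435	2.994194	14.59649	0.205131	0.007573783	0.028769072	DOWN	76
bta-miR-2483-5p	6.7603	20.11475	0.336087	0.012625225	0.046906859	DOWN	194
bta-miR-296-3p	64.49805	136.2474	0.473389	6.70E-07	3.83E-06	DOWN	1881
bta-miR-34a	11.52679	53.05775	0.21725	1.80E-07	1.08E-06	DOWN	2710
bta-miR-34b	8.837222	948.8895	0.009313	1.68E-264	6.12E-263	DOWN	917
bta-miR-34c	108.1892	17155.33	0.006306	0	0	DOWN	1465
bta-miR-375	8.70221	354.1817	0.02457	1.48E-91	3.28E-90	DOWN	351
bta-miR-378	130.7823	265.7867	0.492057	3.23E-11	2.45E-10	DOWN	1821
bta-miR-449a	6.649543	5039.895	0.001319	0	0	DOWN	2360
bta-miR-449b	0.339228	43.3717	0.007821	2.78E-12	2.32E-11	DOWN	2342
bta-miR-449c	1	41.84592	0.023897	1.06E-11	8.55E-11	DOWN	1925
bta-miR-451	93.67503	217.4898	0.43071	4.00E-12	3.28E-11	DOWN	18
bta-miR-484	54.04781	125.1392	0.431901	2.11E-07	1.25E-06	DOWN	3369
bta-miR-486	1142.422	3311.228	0.345015	3.26E-234	1.11E-232	DOWN	847
bta-miR-6123	3.087651	21.62779	0.142763	0.000539356	0.00234643	DOWN	697
bta-miR-6526	1168.153	12648.09	0.092358	0	0	DOWN	2092
bta-miR-767	10.86563	44.6083	0.243579	5.59E-06	2.88E-05	DOWN	1521
bta-miR-9-5p	20.94206	116.7742	0.179338	3.17E-17	3.05E-16	DOWN	261
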