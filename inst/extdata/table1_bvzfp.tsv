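gene_name	locus_id	aa_length	orf_bp	mw	pi	instability	gravy	start	end	group
BvZFP1	LOC104905560	541	1623	58633.75	6.86	57.91	-0.786	10695460	10697687	3i
BvZFP2	LOC125495709	367	1101	41279.25	8.02	55.83	-0.862	10706247	10708429	3i
BvZFP3	LOC104898669	456	1368	50063.48	6.01	60.88	-1.002	36219959	36222487	2i
BvZFP4	LOC104887623	283	849	31507.39	8.21	41.25	-0.667	4757460	4758311	1i
BvZFP5	LOC104906182	543	1629	60544.44	7.17	59.45	-0.701	14363882	14366296	3i
BvZFP6	LOC104886969	186	558	20667.45	8.86	57.6	-0.506	29939770	29940614	2i
BvZFP7	LOC104883124	278	834	30386.53	6.13	59.97	-0.644	45479878	45480934	1i
BvZFP8	LOC104883624	179	537	20615.07	8.3	54.73	-0.976	52215194	52216003	1i
BvZFP9	LOC104906611	170	510	18959.88	6.65	65.03	-0.922	11875979	11876976	1i
BvZFP10	LOC104906657	255	765	28493.69	9.22	57.02	-0.867	11959217	11959984	1i
BvZFP11	LOC104888927	232	696	26701.97	6.89	67.24	-0.791	12886752	12888260	1i
BvZFP12	LOC104906753	304	912	33684.31	8.85	43.09	-1.037	43115842	43118169	1i
BvZFP13	LOC104889553	323	969	35834.41	8.56	58.9	-0.805	51214957	51215928	1i
BvZFP14	LOC104907233	277	831	31391.42	6.2	58.48	-0.972	8025899	8027395	1i
BvZFP15	LOC104890281	572	1716	62896.02	5.69	58.76	-1.132	57253629	57255347	3i
BvZFP16	LOC104894695	162	486	18233.83	6.1	58.33	-1.089	405412	405900	1i
BvZFP17	LOC104893969	496	1488	54927.45	8.48	66.19	-0.718	10823448	10825115	3i
BvZFP18	LOC104892924	177	531	20328.6	5.97	61.13	-0.759	43735292	43736429	1i
BvZFP19	LOC104897252	226	678	25693.54	9.1	57.43	-0.892	10200725	10201830	1i
BvZFP20	LOC104896450	247	741	25939.68	8.64	46.76	-0.604	34971928	34972995	1i
BvZFP21	LOC104896549	220	660	24314.02	7.24	54.26	-0.921	36683224	36687039	1i
BvZFP22	LOC104895813	613	1839	68769.06	6.91	48.17	-1.27	53568797	53571334	4i
BvZFP23	LOC104895001	179	537	19911.57	8.99	75.14	-0.496	63541505	63542044	1i
BvZFP24	LOC104885426	177	531	19942.29	6.15	49.73	-0.751	64317253	64317786	1i
BvZFP25	LOC104885142	165	495	18957.43	7.75	37.2	-0.788	64323220	64323717	1i
BvZFP26	LOC104884472	181	543	20434.76	8.32	43.2	-0.842	64406993	64407538	1i
BvZFP27	LOC104900166	245	735	26613.84	6.01	65.67	-0.521	2250266	2251688	2i
BvZFP28	LOC104908846	340	1020	37135.81	7.75	62.32	-0.839	13404684	13406826	2i
BvZFP29	LOC104899451	204	612	22977.76	8.79	47.89	-0.777	47440915	47443048	1i
BvZFP30	LOC104901462	242	726	25661.67	8.09	62.93	-0.545	21006400	21007514	2i
BvZFP31	LOC104904162	237	711	25331.76	8.55	54.27	-0.358	19929210	19930057	3i
BvZFP32	LOC104904895	299	897	33574.34	8.24	50.67	-0.682	33331932	33333327	1i
BvZFP33	LOC104904924	185	555	21039.05	8.76	59.64	-0.511	33657441	33658524	1i
BvZFP34	LOC104902980	342	1026	37289.83	6.21	58.69	-0.823	44803778	44805047	2i
BvZFP35	LOC104893645	237	711	26905.18	8.52	67.93	-0.792	1955234	1956376	1i
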