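probe	gene	ov_fold	ov_rank	hc_fold	hc_rank	sc_fold	sc_rank	consensus_group	consensus_score	consensus_rank
Oc90	Oc90	15.316797	1	37.191532	36	133.68132	7	OV/HC/SC	44	3
Fbxo2	Fbxo2	14.622012	2	233.46231	3	209.10844	4	OV/HC/SC	9	1
Lmx1a	Lmx1a	11.061509	3	1.071335	7460	2.1826358	1496	OV	8959	1220
Krt1-23	Krt1-23	10.184871	4	1.7182626	2426	7.448142	229	OV/SC	2659	259
Spp1	Spp1	8.454517	5	1.1694639	5352	1.0023074	16967	OV	22324	4802
Cldn6	Cldn6	7.5281053	6	1.8450933	2163	4.1609483	528	OV/SC	2697	264
Wfdc2	Wfdc2	7.073592	7	3.2619166	904	14.833333	88	OV/SC	999	85
Gata3	Gata3	7.0340185	8	17.05958	99	22.630722	39	OV/HC/SC	146	6
Col9a2	Col9a2	6.894713	9	64.73929	16	99.665436	13	OV/HC/SC	38	2
Arhgef19	Arhgef19	6.341925	10	4.2322383	639	14.127765	93	OV/HC/SC	742	49
Rbm35a	Rbm35a	6.3149257	11	2.1024952	1724	4.913607	432	OV/SC	2167	206
Plekhb1	Plekhb1	5.946511	12	28.310795	56	33.40806	25	OV/HC/SC	93	4
Hs3st1	Hs3st1	5.8575263	13	4.9308343	517	22.05582	44	OV/HC/SC	574	33
Rgcc	Rgcc	5.628432	14	4.3943467	600	9.030337	175	OV/HC/SC	789	56
Tbx2	Tbx2	5.626228	15	4.6268463	553	3.1064396	849	OV/HC	1417	119
Prss8	Prss8	5.5848174	16	5.4411964	442	12.075007	123	OV/HC/SC	581	35
Sh3gl2	Sh3gl2	5.195888	17	10.561689	174	11.849528	125	OV/HC/SC	316	10
Wfdc2.2	Wfdc2	5.1527414	18	2.319336	1489	9.602433	161	OV/SC	1668	148
Marveld3	Marveld3	5.006034	19	5.016969	502	9.084135	171	OV/HC/SC	692	45
Vwa2	Vwa2	4.864665	20	1.0021158	10270	5.5677967	364	OV/SC	10654	1500
Bdnf	Bdnf	4.78742	21	9.485823	208	1.0017089	19301	OV/HC	19530	3740
Espn	Espn	4.7623343	22	21.954702	79	1.1772411	5296	OV/HC	5397	653
Plekha4	Plekha4	4.7167573	23	4.1990533	647	6.789616	262	OV/HC/SC	932	75
Fgf10	Fgf10	4.700219	24	13.839492	125	17.822388	64	OV/HC/SC	213	7
Car4	Car4	4.63751	25	3.679346	25122	3.4888153	24946	OV	50093	18760
Prr15	Prr15	4.6330085	26	6.245964	378	7.0138445	249	OV/HC/SC	653	42
Col6a1	Col6a1	4.622068	27	1.2619317	21404	1.151628	5720	OV	27151	7232
Six1	Six1	4.5915775	28	5.8167586	403	5.891639	328	OV/HC/SC	759	52
Socs2	Socs2	4.547705	29	5.1087866	493	5.8204165	339	OV/HC/SC	861	64
Myo7a	Myo7a	4.538013	30	28.857481	55	1.0124729	11440	OV/HC	11525	1651
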