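probe	gene	ov_mean	ov_sd	ov_fold	ov_q	ov_rank	ref_fold_abs	ref_upreg
Oc90	Oc90	10.97366167	0.419246795	15.316797	2.08E-09	1	1.132771783	NS
Fbxo2	Fbxo2	10.87404333	0.072690153	14.622012	1.74E-12	2	1.023630354	NS
Lmx1a	Lmx1a	11.06934217	0.056113649	11.061509	3.38E-04	3	1.448138913	Periotic
Krt1-23	Krt1-23	10.25196333	0.288855995	10.184871	2.04E-09	4	1.220269579	NS
Spp1	Spp1	9.971883833	0.332888479	8.454517	1.67E-10	5	1.136606365	NS
Cldn6	Cldn6	13.18188567	0.089216859	7.5281053	3.69E-08	6	2.35525402	Embryo
Wfdc2	Wfdc2	13.53477267	0.213203	7.073592	5.33E-09	7	2.496286749	Embryo
Gata3	Gata3	11.364921	0.142121662	7.0340185	1.49E-09	8	1.173139844	NS
Col9a2	Col9a2	10.07369633	0.153509332	6.894713	1.49E-09	9	1.008878076	NS
Arhgef19	Arhgef19	9.768474333	0.09629171	6.341925	2.08E-09	10	1.218514062	NS
Rbm35a	Rbm35a	12.29022383	0.143019237	6.3149257	6.10E-09	11	2.368308192	Embryo
Plekhb1	Plekhb1	10.08439517	0.16829363	5.946511	6.30E-11	12	1.312607244	NS
Hs3st1	Hs3st1	10.46399633	0.195136572	5.8575263	2.70E-09	13	1.048332013	No
Rgcc	Rgcc	10.77107167	0.161833702	5.628432	1.19E-08	14	1.990202734	Embryo
Tbx2	Tbx2	9.984906	0.297733516	5.626228	9.24E-08	15	1.702381408	Embryo
Prss8	Prss8	10.105778	0.16620698	5.5848174	1.45E-07	16	1.290586405	NS
Sh3gl2	Sh3gl2	9.860674833	0.135098031	5.195888	8.67E-11	17	1.002118118	NS
Wfdc2.2	Wfdc2	9.499769333	0.302036446	5.1527414	2.46E-08	18	1.227582286	NS
Marveld3	Marveld3	9.041756667	0.133118972	5.006034	3.82E-09	19	1.094974091	NS
Vwa2	Vwa2	9.691604	0.165306445	4.864665	5.78E-08	20	1.376504348	NS
Bdnf	Bdnf	9.836624667	0.178453967	4.78742	8.09E-09	21	1.246577778	NS
Espn	Espn	10.76721233	0.250324449	4.7623343	1.19E-08	22	2.301431921	Embryo
Plekha4	Plekha4	9.914148	0.299348822	4.7167573	8.07E-09	23	1.282688658	NS
Fgf10	Fgf10	10.70834767	0.021669661	4.700219	2.49E-09	24	2.193222734	Embryo
Car4	Car4	10.77693067	0.369327027	4.63751	2.23E-06	25	1.171838835	NS
Prr15	Prr15	9.310321667	0.225649081	4.6330085	2.20E-08	26	1.146866527	NS
Col6a1	Col6a1	10.12810567	0.204186116	4.622068	2.27E-09	27	1.199047241	NS
Six1	Six1	11.91456133	0.035842889	4.5915775	2.49E-09	28	1.492275252	Embryo
Socs2	Socs2	12.39277283	0.234257353	4.547705	2.49E-09	29	1.097722074	NS
Myo7a	Myo7a	9.023172167	0.481244122	4.538013	1.31E-07	30	1.027957463	NS
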