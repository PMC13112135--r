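case	n	ri	ari	nmi	ami
1	27	0.632478632479	0.017787804508	0.337746166989	0.046727810216
2	16	0.858333333333	0.030418250951	0.714895731608	0.038523720152
3	29	0.798029556650	-0.014257860102	0.494069587001	-0.018887115144
4	15	0.695238095238	-0.020036429872	0.452670107409	-0.024635304293
5	6	0.666666666667	0.000000000000	0.000000000000	0.000000000000
6	9	0.222222222222	0.000000000000	0.000000000000	0.000000000000
7	7	0.333333333333	-0.020833333333	0.240733559312	-0.044165502477
8	10	0.577777777778	-0.021505376344	0.492514450491	-0.017632759211
9	24	0.608695652174	0.041420118343	0.225989134739	0.043003872159
10	10	0.644444444444	-0.016949152542	0.417533669156	-0.002078995727
11	12	0.727272727273	0.057142857143	0.677741527920	0.121666656091
12	27	0.056980056980	0.000000000000	0.000000000000	0.000000000000
13	6	0.400000000000	-0.363636363636	0.301663115996	-0.508930480659
14	17	0.727941176471	-0.031147540984	0.483126700077	-0.039216341043
15	28	0.825396825397	0.001201056930	0.563079983015	0.003289194850
16	23	0.766798418972	0.099535500995	0.473198182991	0.140362993090
17	6	0.533333333333	-0.129032258065	0.410050859030	-0.161456743397
18	29	0.906403940887	-0.048952950775	0.719192372851	-0.060392859652
19	16	0.283333333333	0.000000000000	0.000000000000	0.000000000000
20	20	0.847368421053	0.002173125679	0.691916267156	0.005452545588
21	26	0.855384615385	-0.022080963533	0.627242693369	-0.030700664402
22	8	0.535714285714	0.010869565217	0.407843370189	0.017159767480
23	26	0.541538461538	0.091378178065	0.177981247120	0.075883862085
24	25	0.913333333333	-0.044176706827	0.754453184924	-0.050331729317
25	16	0.883333333333	-0.060606060606	0.766090677557	-0.070174538461
26	20	0.868421052632	0.003357112883	0.691916267156	0.005195824879
27	23	0.877470355731	-0.053175775480	0.707268157558	-0.070650715368
28	18	0.797385620915	0.058368076236	0.591849664626	0.040242995359
29	29	0.879310344828	0.011527377522	0.667976446587	0.018675313329
30	14	0.087912087912	0.000000000000	0.000000000000	0.000000000000
31	18	0.771241830065	-0.020583190395	0.533331213915	-0.019954675805
32	10	0.844444444444	0.136986301370	0.743278095726	0.148374570469
33	5	0.500000000000	-0.190476190476	0.394728335176	-0.223623362284
34	30	0.843678160920	-0.067176563966	0.532079434923	-0.099049265080
35	18	0.830065359477	-0.090460526316	0.614423723621	-0.113520485438
36	26	0.824615384615	0.005902870942	0.593826191801	0.019300394311
37	13	0.756410256410	-0.138248847926	0.546906043421	-0.175493953118
38	16	0.825000000000	0.000000000000	0.655470385290	0.001955467693
39	16	0.850000000000	0.125506072874	0.730027365206	0.169508062025
40	10	0.866666666667	0.328358208955	0.835279645259	0.416865876332
41	14	0.780219780220	-0.029411764706	0.591187365558	-0.035462492048
42	7	0.476190476190	-0.115942028986	0.162788708592	-0.124047810497
43	18	0.836601307190	-0.081424936387	0.680319632540	-0.111015392223
44	29	0.756157635468	0.013159833047	0.494774187832	0.029647616912
45	18	0.496732026144	-0.012026458208	0.239990751228	0.017814609991
46	25	0.723333333333	0.113879003559	0.485616184156	0.186081428941
47	25	0.460000000000	-0.004962779156	0.132618105009	-0.005812256496
48	21	0.842857142857	-0.049046321526	0.656958865163	-0.069212384026
49	15	1.000000000000	1.000000000000	1.000000000000	1.000000000000
50	30	0.836781609195	-0.025977477328	0.609560977015	-0.042349192961
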