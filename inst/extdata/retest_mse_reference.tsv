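subject	mse_raw	mse_mean	mse_shrinkage
1	0.2183	0.1342	0.1336
2	0.1929	0.0981	0.0975
3	0.1313	0.0854	0.0851
4	0.2520	0.1127	0.1114
5	0.2313	0.1137	0.1125
6	0.2317	0.1639	0.1629
7	0.1440	0.0985	0.0955
8	0.2052	0.1082	0.1081
9	0.2149	0.1241	0.1237
10	0.1725	0.1033	0.1030
11	0.4163	0.1572	0.1570
12	0.1961	0.0876	0.0873
13	0.2199	0.1411	0.1406
14	0.2625	0.1566	0.1553
15	0.1035	0.0641	0.0640
16	0.2858	0.0630	0.0629
17	0.1317	0.1157	0.1151
18	0.3384	0.1032	0.1022
19	0.1861	0.0753	0.0751
20	0.2052	0.1372	0.1366
21	0.2025	0.1074	0.1070
Average	0.2169	0.1118	0.1103
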