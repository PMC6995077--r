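kind	position	guide_base	site_base	pam2	penalty
mismatch	1	A	C	NA	0.3
mismatch	1	A	G	NA	0.5
mismatch	1	A	T	NA	0.25
mismatch	1	C	A	NA	0.3
mismatch	1	C	G	NA	0.15
mismatch	1	C	T	NA	0.45
mismatch	1	G	A	NA	0.55
mismatch	1	G	C	NA	0.15
mismatch	1	G	T	NA	1
mismatch	1	T	A	NA	0.25
mismatch	1	T	C	NA	0.5
mismatch	1	T	G	NA	1
mismatch	2	A	C	NA	0.2866
mismatch	2	A	G	NA	0.4776
mismatch	2	A	T	NA	0.2388
mismatch	2	C	A	NA	0.2866
mismatch	2	C	G	NA	0.1433
mismatch	2	C	T	NA	0.4299
mismatch	2	G	A	NA	0.5254
mismatch	2	G	C	NA	0.1433
mismatch	2	G	T	NA	1
mismatch	2	T	A	NA	0.2388
mismatch	2	T	C	NA	0.4776
mismatch	2	T	G	NA	0.812
mismatch	3	A	C	NA	0.2732
mismatch	3	A	G	NA	0.4553
mismatch	3	A	T	NA	0.2276
mismatch	3	C	A	NA	0.2732
mismatch	3	C	G	NA	0.1366
mismatch	3	C	T	NA	0.4097
mismatch	3	G	A	NA	0.5008
mismatch	3	G	C	NA	0.1366
mismatch	3	G	T	NA	0.8195
mismatch	3	T	A	NA	0.2276
mismatch	3	T	C	NA	0.4553
mismatch	3	T	G	NA	1
mismatch	4	A	C	NA	0.2597
mismatch	4	A	G	NA	0.4329
mismatch	4	A	T	NA	0.2164
mismatch	4	C	A	NA	0.2597
mismatch	4	C	G	NA	0.1299
mismatch	4	C	T	NA	0.3896
mismatch	4	G	A	NA	0.4762
mismatch	4	G	C	NA	0.1299
mismatch	4	G	T	NA	0.7792
mismatch	4	T	A	NA	0.2164
mismatch	4	T	C	NA	0.4329
mismatch	4	T	G	NA	0.7359
mismatch	5	A	C	NA	0.2463
mismatch	5	A	G	NA	0.4105
mismatch	5	A	T	NA	0.2053
mismatch	5	C	A	NA	0.2463
mismatch	5	C	G	NA	0.1232
mismatch	5	C	T	NA	0.3695
mismatch	5	G	A	NA	0.4516
mismatch	5	G	C	NA	0.1232
mismatch	5	G	T	NA	0.7389
mismatch	5	T	A	NA	0.2053
mismatch	5	T	C	NA	0.4105
mismatch	5	T	G	NA	0.6979
mismatch	6	A	C	NA	0.2329
mismatch	6	A	G	NA	0.3882
mismatch	6	A	T	NA	0.1941
mismatch	6	C	A	NA	0.2329
mismatch	6	C	G	NA	0.1164
mismatch	6	C	T	NA	0.3493
mismatch	6	G	A	NA	0.427
mismatch	6	G	C	NA	0.1164
mismatch	6	G	T	NA	0.6987
mismatch	6	T	A	NA	0.1941
mismatch	6	T	C	NA	0.3882
mismatch	6	T	G	NA	0.6599
mismatch	7	A	C	NA	0.2195
mismatch	7	A	G	NA	0.3658
mismatch	7	A	T	NA	0.1829
mismatch	7	C	A	NA	0.2195
mismatch	7	C	G	NA	0.1097
mismatch	7	C	T	NA	0.3292
mismatch	7	G	A	NA	0.4024
mismatch	7	G	C	NA	0.1097
mismatch	7	G	T	NA	0.6584
mismatch	7	T	A	NA	0.1829
mismatch	7	T	C	NA	0.3658
mismatch	7	T	G	NA	0.6218
mismatch	8	A	C	NA	0.2061
mismatch	8	A	G	NA	0.3434
mismatch	8	A	T	NA	0.1717
mismatch	8	C	A	NA	0.2061
mismatch	8	C	G	NA	0.103
mismatch	8	C	T	NA	0.3091
mismatch	8	G	A	NA	0.3778
mismatch	8	G	C	NA	0.103
mismatch	8	G	T	NA	0.6182
mismatch	8	T	A	NA	0.1717
mismatch	8	T	C	NA	0.3434
mismatch	8	T	G	NA	0.5838
mismatch	9	A	C	NA	0.1926
mismatch	9	A	G	NA	0.3211
mismatch	9	A	T	NA	0.1605
mismatch	9	C	A	NA	0.1926
mismatch	9	C	G	NA	0.0963
mismatch	9	C	T	NA	0.2889
mismatch	9	G	A	NA	0.3532
mismatch	9	G	C	NA	0.0963
mismatch	9	G	T	NA	0.5779
mismatch	9	T	A	NA	0.1605
mismatch	9	T	C	NA	0.3211
mismatch	9	T	G	NA	0.5458
mismatch	10	A	C	NA	0.1792
mismatch	10	A	G	NA	0.2987
mismatch	10	A	T	NA	0.1493
mismatch	10	C	A	NA	0.1792
mismatch	10	C	G	NA	0.0896
mismatch	10	C	T	NA	0.2688
mismatch	10	G	A	NA	0.3286
mismatch	10	G	C	NA	0.0896
mismatch	10	G	T	NA	0.5376
mismatch	10	T	A	NA	0.1493
mismatch	10	T	C	NA	0.2987
mismatch	10	T	G	NA	0.5078
mismatch	11	A	C	NA	0.1658
mismatch	11	A	G	NA	0.2763
mismatch	11	A	T	NA	0.1382
mismatch	11	C	A	NA	0.1658
mismatch	11	C	G	NA	0.0829
mismatch	11	C	T	NA	0.2487
mismatch	11	G	A	NA	0.3039
mismatch	11	G	C	NA	0.0829
mismatch	11	G	T	NA	0.4974
mismatch	11	T	A	NA	0.1382
mismatch	11	T	C	NA	0.2763
mismatch	11	T	G	NA	0.4697
mismatch	12	A	C	NA	0.1524
mismatch	12	A	G	NA	0.2539
mismatch	12	A	T	NA	0.127
mismatch	12	C	A	NA	0.1524
mismatch	12	C	G	NA	0.0762
mismatch	12	C	T	NA	0.2286
mismatch	12	G	A	NA	0.2793
mismatch	12	G	C	NA	0.0762
mismatch	12	G	T	NA	0.4571
mismatch	12	T	A	NA	0.127
mismatch	12	T	C	NA	0.2539
mismatch	12	T	G	NA	0.4317
mismatch	13	A	C	NA	0.1389
mismatch	13	A	G	NA	0.2316
mismatch	13	A	T	NA	0.1158
mismatch	13	C	A	NA	0.1389
mismatch	13	C	G	NA	0.0695
mismatch	13	C	T	NA	0.2084
mismatch	13	G	A	NA	0.2547
mismatch	13	G	C	NA	0.0695
mismatch	13	G	T	NA	0.4168
mismatch	13	T	A	NA	0.1158
mismatch	13	T	C	NA	0.2316
mismatch	13	T	G	NA	0.3937
mismatch	14	A	C	NA	0.1255
mismatch	14	A	G	NA	0.2092
mismatch	14	A	T	NA	0.1046
mismatch	14	C	A	NA	0.1255
mismatch	14	C	G	NA	0.0628
mismatch	14	C	T	NA	0.1883
mismatch	14	G	A	NA	0.2301
mismatch	14	G	C	NA	0.0628
mismatch	14	G	T	NA	0.3766
mismatch	14	T	A	NA	0.1046
mismatch	14	T	C	NA	0.2092
mismatch	14	T	G	NA	0.3557
mismatch	15	A	C	NA	0.1121
mismatch	15	A	G	NA	0.1868
mismatch	15	A	T	NA	0.0934
mismatch	15	C	A	NA	0.1121
mismatch	15	C	G	NA	0.0561
mismatch	15	C	T	NA	0.1682
mismatch	15	G	A	NA	0.2055
mismatch	15	G	C	NA	0.0561
mismatch	15	G	T	NA	0.3363
mismatch	15	T	A	NA	0.0934
mismatch	15	T	C	NA	0.1868
mismatch	15	T	G	NA	0.3176
mismatch	16	A	C	NA	0.0987
mismatch	16	A	G	NA	0.1645
mismatch	16	A	T	NA	0.0822
mismatch	16	C	A	NA	0.0987
mismatch	16	C	G	NA	0.0493
mismatch	16	C	T	NA	0.148
mismatch	16	G	A	NA	0.1809
mismatch	16	G	C	NA	0.0493
mismatch	16	G	T	NA	0.2961
mismatch	16	T	A	NA	0.0822
mismatch	16	T	C	NA	0.1645
mismatch	16	T	G	NA	0.2796
mismatch	17	A	C	NA	0.0853
mismatch	17	A	G	NA	0.1421
mismatch	17	A	T	NA	0.0711
mismatch	17	C	A	NA	0.0853
mismatch	17	C	G	NA	0.0426
mismatch	17	C	T	NA	0.1279
mismatch	17	G	A	NA	0.1563
mismatch	17	G	C	NA	0.0426
mismatch	17	G	T	NA	0.2558
mismatch	17	T	A	NA	0.0711
mismatch	17	T	C	NA	0.1421
mismatch	17	T	G	NA	0.2416
mismatch	18	A	C	NA	0.0718
mismatch	18	A	G	NA	0.1197
mismatch	18	A	T	NA	0.0599
mismatch	18	C	A	NA	0.0718
mismatch	18	C	G	NA	0.0359
mismatch	18	C	T	NA	0.1078
mismatch	18	G	A	NA	0.1317
mismatch	18	G	C	NA	0.0359
mismatch	18	G	T	NA	0.2155
mismatch	18	T	A	NA	0.0599
mismatch	18	T	C	NA	0.1197
mismatch	18	T	G	NA	0.2036
mismatch	19	A	C	NA	0.0584
mismatch	19	A	G	NA	0.0974
mismatch	19	A	T	NA	0.0487
mismatch	19	C	A	NA	0.0584
mismatch	19	C	G	NA	0.0292
mismatch	19	C	T	NA	0.0876
mismatch	19	G	A	NA	0.1071
mismatch	19	G	C	NA	0.0292
mismatch	19	G	T	NA	0.1753
mismatch	19	T	A	NA	0.0487
mismatch	19	T	C	NA	0.0974
mismatch	19	T	G	NA	0.1655
mismatch	20	A	C	NA	0.045
mismatch	20	A	G	NA	0.075
mismatch	20	A	T	NA	0.0375
mismatch	20	C	A	NA	0.045
mismatch	20	C	G	NA	0.0225
mismatch	20	C	T	NA	0.0675
mismatch	20	G	A	NA	0.0825
mismatch	20	G	C	NA	0.0225
mismatch	20	G	T	NA	0.135
mismatch	20	T	A	NA	0.0375
mismatch	20	T	C	NA	0.075
mismatch	20	T	G	NA	0.1275
pam	NA	NA	NA	AA	0
pam	NA	NA	NA	AC	0
pam	NA	NA	NA	AG	0.26
pam	NA	NA	NA	AT	0
pam	NA	NA	NA	CA	0
pam	NA	NA	NA	CC	0
pam	NA	NA	NA	CG	0.02
pam	NA	NA	NA	CT	0
pam	NA	NA	NA	GA	0.07
pam	NA	NA	NA	GC	0
pam	NA	NA	NA	GG	1
pam	NA	NA	NA	GT	0.02
pam	NA	NA	NA	TA	0
pam	NA	NA	NA	TC	0
pam	NA	NA	NA	TG	0.04
pam	NA	NA	NA	TT	0
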