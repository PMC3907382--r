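chrom	n_cnvrs	n_genes	cnvr_bp	chrom_bp
1	22	59	1486385	185838109
2	12	11	471323	120857687
3	14	8	339820	119479920
4	23	11	685515	108569075
5	12	12	407652	99680356
6	13	8	188057	84719076
7	22	48	940910	98542428
8	24	30	1034813	94057673
9	6	3	142125	83561422
10	17	18	338576	83980604
11	9	12	161560	61308211
12	6	171	2611353	33091231
13	9	13	196374	42578167
14	9	4	291428	93904894
15	6	1	77346	91571448
16	7	3	131240	87365405
17	17	2	194530	80757907
18	14	8	410207	82527541
19	7	6	138162	59975221
20	37	48	1526667	64166202
21	2	3	78028	57723302
22	9	4	265150	49946797
23	12	3	173586	55726280
24	5	1	89110	46749900
25	8	10	271071	39536964
26	10	8	251810	41866177
27	9	6	176564	39960074
28	7	4	469128	46177339
29	5	3	38069	33672925
30	0	0	0	30062385
31	0	0	0	24984650
X	0	0	0	124114077
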