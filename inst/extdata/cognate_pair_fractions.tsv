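pair_index	npp_gene	npgpcr_gene	galpha_family	fraction_of_type_pairs
1	Npy	Npy1r	Gi/o	0.7805
2	Npy	Npy2r	Gi/o	0.341
3	Npy	Npy5r	Gi/o	0.8095
4	Sst	Sstr1	Gi/o	0.751
5	Sst	Sstr2	Gi/o	0.836
6	Sst	Sstr3	Gi/o	0.405
7	Sst	Sstr4	Gi/o	0.806
8	Penk	Oprd1	Gi/o	0.4955
9	Penk	Oprm1	Gi/o	0.9
10	Cort	Sstr1	Gi/o	0.6265
11	Cort	Sstr2	Gi/o	0.6965
12	Cort	Sstr3	Gi/o	0.338
13	Cort	Sstr4	Gi/o	0.672
14	Pdyn	Oprd1	Gi/o	0.2115
15	Pdyn	Oprk1	Gi/o	0.0745
16	Pdyn	Oprm1	Gi/o	0.4
17	Pnoc	Oprl1	Gi/o	0.654
18	Rln1	Rxfp3	Gi/o	0.106
19	Vip	Vipr1	Gs	0.496
20	Vip	Vipr2	Gs	0.052
21	Crh	Crhr1	Gs	0.3925
22	Crh	Crhr2	Gs	0.2035
23	Rln1	Rxfp1	Gs	0.2465
24	Rln1	Rxfp2	Gs	0.07
25	Adcyap1	Adcyap1r1	Gs	0.284
26	Adcyap1	Vipr1	Gs	0.1465
27	Adcyap1	Vipr2	Gs	0.0155
28	Tac2	Tacr3	Gq/11	0.0955
29	Cck	Cckbr	Gq/11	0.6635
30	Tac1	Tacr1	Gq/11	0.119
31	Pthlh	Pth1r	Gq/11	0.392
32	Trh	Trhr	Gq/11	0.016
33	Trh	Trhr2	Gq/11	0.055
34	Grp	Grpr	Gq/11	0.113
35	Nts	Ntsr1	Gq/11	0.0225
36	Nts	Ntsr2	Gq/11	0.054
37	Nmb	Nmbr	Gq/11	0.5655
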