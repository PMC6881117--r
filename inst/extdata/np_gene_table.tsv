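gene	role	galpha_family	cognate_partners	peak_fpkm	pfpkm_percentile	pfpkm_rank	pct_cells	predicted_products
Npy	NPP	NA	Npy1r|Npy2r|Npy5r	108865	100.00	1	42	Neuropeptide Y
Sst	NPP	NA	Sstr1|Sstr2|Sstr3|Sstr4	70274	99.99	2	26	Somatostatins
Vip	NPP	NA	Vipr1|Vipr2	48747	99.99	3	33	Vasoactive Intestinal Peptide
Tac2	NPP	NA	Tacr3	18284	99.98	4	15	Neurokinin B
Cck	NPP	NA	Cckbr	16396	99.97	6	69	Cholecystokinins
Penk	NPP	NA	Oprd1|Oprm1	11160	99.96	8	26	Enkephalins
Crh	NPP	NA	Crhr1|Crhr2	9118	99.95	10	17	Corticotropin-Releasing Hormone
Cort	NPP	NA	Sstr1|Sstr2|Sstr3|Sstr4	7477	99.93	15	32	Cortistatin
Tac1	NPP	NA	Tacr1	5728	99.92	18	11	Substance P, Neurokinin A
Pdyn	NPP	NA	Oprd1|Oprk1|Oprm1	2813	99.69	68	8	Dynorphins
Pthlh	NPP	NA	Pth1r	1656	99.29	156	18	Parathyroid-Hormone-Like Hormone
Pnoc	NPP	NA	Oprl1	698	97.68	509	23	Nociceptins
Trh	NPP	NA	Trhr|Trhr2	510	96.51	766	3	Thyrotropin-Releasing Hormone
Grp	NPP	NA	Grpr	435	95.59	968	12	Gastrin-Releasing Peptide
Rln1	NPP	NA	Rxfp1|Rxfp2|Rxfp3	258	91.99	1757	7	Relaxin 1
Adcyap1	NPP	NA	Adcyap1r1|Vipr1|Vipr2	165	87.29	2788	26	Adenylate Cyclase-Activating Polypeptides
Nts	NPP	NA	Ntsr1|Ntsr2	121	82.14	3917	1	Neurotensin
Nmb	NPP	NA	Nmbr	112	80.53	4270	14	Neuromedin B
Sstr2	NP-GPCR	Gi/o	Sst|Cort	413	95.3	NA	42	Somatostatin Receptor 2
Npy2r	NP-GPCR	Gi/o	Npy	291	93.1	NA	10	Neuropeptide Y Receptor Y2
Npy1r	NP-GPCR	Gi/o	Npy	272	92.4	NA	50	Neuropeptide Y Receptor Y1
Grpr	NP-GPCR	Gq/11	Grp	231	91	NA	10	GRP Receptor
Cckbr	NP-GPCR	Gq/11	Cck	210	90	NA	52	Cholecystokinin B Receptor
Ntsr2	NP-GPCR	Gq/11	Nts	161	86.9	NA	17	Neurotensin Receptor 2
Npy5r	NP-GPCR	Gi/o	Npy	152	86.1	NA	28	Neuropeptide Y Receptor Y5
Nmbr	NP-GPCR	Gq/11	Nmb	123	82.4	NA	8	Neuromedin B Receptor
Rxfp1	NP-GPCR	Gs	Rln1	121	82	NA	22	Relaxin Family Receptor 1
Sstr4	NP-GPCR	Gi/o	Sst|Cort	106	79.5	NA	28	Somatostatin Receptor 4
Trhr	NP-GPCR	Gq/11	Trh	101	78.4	NA	3	TRH Receptor
Sstr1	NP-GPCR	Gi/o	Sst|Cort	90	76	NA	38	Somatostatin Receptor 1
Adcyap1r1	NP-GPCR	Gs	Adcyap1	89	75.8	NA	71	ADCYAP1 Receptor 1
Crhr1	NP-GPCR	Gs	Crh	86	74.9	NA	28	CRH Receptor 1
Rxfp3	NP-GPCR	Gi/o	Rln1	85	74.7	NA	5	Relaxin Family Receptor 3
Oprl1	NP-GPCR	Gi/o	Pnoc	82	73.8	NA	48	Opioid Receptor-Like 1
Crhr2	NP-GPCR	Gs	Crh	72	70.7	NA	3	CRH Receptor 2
Tacr3	NP-GPCR	Gq/11	Tac2	65	68	NA	3	Tachykinin Receptor 3
Oprk1	NP-GPCR	Gi/o	Pdyn	64	67.4	NA	3	Kappa-Opioid Receptor
Tacr1	NP-GPCR	Gq/11	Tac1	56	64.2	NA	3	Tachykinin Receptor 1
Pth1r	NP-GPCR	Gq/11	Pthlh	51	61.6	NA	15	PTH 1 Receptor
Vipr1	NP-GPCR	Gs	Vip|Adcyap1	41	56.1	NA	28	VIP Receptor 1
Oprm1	NP-GPCR	Gi/o	Penk|Pdyn	35	52.1	NA	43	Mu-Opioid Receptor
Trhr2	NP-GPCR	Gq/11	Trh	30	48.9	NA	10	TRH Receptor 2
Vipr2	NP-GPCR	Gs	Vip|Adcyap1	30	48.4	NA	0.5	VIP Receptor 2
Rxfp2	NP-GPCR	Gs	Rln1	28	47.3	NA	4	Relaxin Family Receptor 2
Oprd1	NP-GPCR	Gi/o	Penk|Pdyn	26	45.8	NA	13	Delta-Opioid Receptor
Ntsr1	NP-GPCR	Gq/11	Nts	24	44.3	NA	10	Neurotensin Receptor 1
Sstr3	NP-GPCR	Gi/o	Sst|Cort	17	39.5	NA	21	Somatostatin Receptor 3
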