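gene_id	gene_symbol	human_ortholog	condition	direction	n_designs	avg_z	tier
FBgn0039830	ATPsynC	ATP5G2	control	down	2	-2.17	high
FBgn0026872	CG14777	MPV17L	control	down	2	-1.82	high
FBgn0051663	CG31663		control	down	2	-1.58	high
FBgn0052512	CG32512	TMEM205	control	down	2	-2.49	high
FBgn0039223	CG5805	SLC25A44	control	down	2	-1.97	high
FBgn0032833	COX4	COX4I1,2	control	down	2	-1.76	high
FBgn0040529	COX7A	COX7A2	control	down	2	-2.02	high
FBgn0062413	Ctr1A	SLC31A1	control	down	2	-2.06	high
FBgn0262743	Fs(2)Ket	KPNB1	control	down	2	-3.91	high
FBgn0024319	Nach	SCNN1B,G	control	down	2	-1.89	high
FBgn0035382	Or63a		control	down	2	-1.73	high
FBgn0021906	RFeSP	UQCRFS1	control	down	2	-2.93	high
FBgn0266098	rg	NBEA	control	down	2	-1.82	high
FBgn0003360	sesB	SLC25A4	control	down	2	-1.83	high
FBgn0025725	alphaCOP	COPA	control	up	2	2.11	high
FBgn0038415	CG17929		control	up	2	2.17	high
FBgn0264907	CG44098		control	up	2	1.76	high
FBgn0027556	CG4928	UNC93A	control	up	2	1.99	high
FBgn0036742	CG7497	PTGER1,3,4	control	up	2	1.71	high
FBgn0034438	CG9416	ERMP1	control	up	2	1.85	high
FBgn0043903	dome		control	up	2	1.82	high
FBgn0000636	Fas3		control	up	2	2.97	high
FBgn0001179	hay	ERCC3	control	up	2	3.19	high
FBgn0263782	Hmgcr	HMGCR	control	up	2	2.59	high
FBgn0051072	Lerp	IGF2R	control	up	2	1.69	high
FBgn0259214	PMCA	ATP2B1,2,3,4	control	up	2	2.29	high
FBgn0032006	Pvr	FLT1	control	up	2	5.12	high
FBgn0086357	Sec61alpha	SEC61A1,2	control	up	2	2.48	high
FBgn0011708	Syx5	STX5	control	up	3	2.87	high
FBgn0021796	Tor	MTOR	control	up	2	2.51	high
FBgn0039644	rdog	ABCC family	ZnCl2	down	2	-1.81	high
FBgn0025725	alphaCOP	COPA	ZnCl2	up	3	2.47	high
FBgn0270926	AsnS	ASNS	ZnCl2	up	2	1.85	high
FBgn0052672	Atg8a	GABARAP	ZnCl2	up	2	2.20	high
FBgn0025724	beta'COP	COPB2	ZnCl2	up	3	2.54	high
FBgn0263979	Caf1-55	RBBP4,7	ZnCl2	up	2	2.09	high
FBgn0030996	CG14194	TMEM185A,B	ZnCl2	up	2	3.22	high
FBgn0039045	CG17119	CTNS	ZnCl2	up	2	4.88	high
FBgn0052000	CG32000	ATP13A2,3,4,5	ZnCl2	up	3	4.14	high
FBgn0051116	ClC-a	CLCN1,2	ZnCl2	up	2	3.04	high
FBgn0002183	dre4	SUPT16H	ZnCl2	up	3	3.30	high
FBgn0037249	eIF3-S10	EIF3A	ZnCl2	up	3	2.22	high
FBgn0020443	Elf	GSPT1,2	ZnCl2	up	2	1.72	high
FBgn0024236	foi	SLC39A family	ZnCl2	up	2	3.42	high
FBgn0001179	hay	ERCC3	ZnCl2	up	2	3.21	high
FBgn0014189	Hel25E	DDX39A,B	ZnCl2	up	3	7.74	high
FBgn0031294	IA-2	PTPRN,N2	ZnCl2	up	2	2.54	high
FBgn0284253	LeuRS	LARS,LARS2	ZnCl2	up	2	1.73	high
FBgn0034641	mahj	DCAF1	ZnCl2	up	3	1.87	high
FBgn0259111	Ndae1	SLC4A family	ZnCl2	up	2	1.60	high
FBgn0039125	Ndc1	NDC1	ZnCl2	up	2	1.87	high
FBgn0039004	Nup133	NUP133	ZnCl2	up	2	3.01	high
FBgn0021761	Nup154	NUP155	ZnCl2	up	3	2.69	high
FBgn0039302	Nup358	RANBP2	ZnCl2	up	2	3.17	high
FBgn0027537	Nup93-1	NUP93	ZnCl2	up	2	5.60	high
FBgn0039120	Nup98-96	NUP98	ZnCl2	up	2	6.02	high
FBgn0260962	pic	DDB1	ZnCl2	up	3	3.22	high
FBgn0264978	Slh	SCFD1	ZnCl2	up	2	1.58	high
FBgn0283469	Vps4	VPS4A,B	ZnCl2	up	2	4.60	high
FBgn0010217	ATPsynbeta	ATP5B	MnCl2	down	2	-2.45	high
FBgn0030263	CG2076	GHITM	MnCl2	down	2	-1.63	high
FBgn0039223	CG5805	SLC25A44	MnCl2	down	2	-1.80	high
FBgn0030768	CG9723	NEMP1,2	MnCl2	down	2	-1.79	high
FBgn0062413	Ctr1A	SLC31A1	MnCl2	down	3	-1.90	high
FBgn0264000	GluRIB	GRIA1,2,3,4	MnCl2	down	2	-1.57	high
FBgn0029870	Marf	MFN2	MnCl2	down	2	-2.81	high
FBgn0039302	Nup358	RANBP2	MnCl2	down	2	-2.17	high
FBgn0036770	Prestin	SLC26A5	MnCl2	down	2	-2.46	high
FBgn0021906	RFeSP	UQCRFS1	MnCl2	down	2	-2.74	high
FBgn0036260	Rh7	OPN4,3	MnCl2	down	2	-2.09	high
FBgn0027603	Ulp1	SENP1,2,3,5	MnCl2	down	2	-1.83	high
FBgn0031937	CG13795		MnCl2	up	2	3.32	high
FBgn0030030	CG1636		MnCl2	up	2	3.20	high
FBgn0039045	CG17119	CTNS	MnCl2	up	2	2.38	high
FBgn0250757	CG42235	SLC5A family	MnCl2	up	3	2.92	high
FBgn0027556	CG4928	UNC93A	MnCl2	up	2	1.71	high
FBgn0034275	CG5002	SLC26A11	MnCl2	up	2	1.81	high
FBgn0037764	CG9459	ELOVL7	MnCl2	up	2	2.36	high
FBgn0042701	CR12628		MnCl2	up	2	3.10	high
FBgn0061492	loj	TMED6	MnCl2	up	2	1.95	high
FBgn0025814	Mgstl	MGST1	MnCl2	up	2	3.10	high
FBgn0052475	mthl8		MnCl2	up	2	2.38	high
FBgn0032006	Pvr	FLT1	MnCl2	up	2	3.46	high
FBgn0031760	Tsp26A	TSPAN5	MnCl2	up	2	1.99	high
FBgn0029508	Tsp42Ea	CD63	MnCl2	up	2	2.92	high
FBgn0033136	Tsp42Eo		MnCl2	up	2	2.59	high
FBgn0033137	Tsp42Ep		MnCl2	up	2	2.37	high
FBgn0033139	Tsp42Er		MnCl2	up	2	1.98	high
FBgn0022097	Vha36-1	ATP6V1D	MnCl2	up	2	1.64	high
FBgn0040377	Vha36-3	ATP6V1D	MnCl2	up	2	2.21	high
FBgn0262511	Vha44	ATP6V1C1	MnCl2	up	2	2.05	high
FBgn0263598	Vha68-2	ATP6V1A	MnCl2	up	2	2.57	high
FBgn0028662	VhaPPA1-1	ATP6V0B	MnCl2	up	2	1.99	high
FBgn0027779	VhaSFD	ATP6V1H	MnCl2	up	3	2.37	high
FBgn0035432	ZnT63C	SLC30A1	MnCl2	up	2	2.27	high
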