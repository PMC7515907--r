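seed	k_known	n_novel	novel_partners
AHI1	1	2	ARFGEF3,IFNGR1
AK7	0	3	BEGAIN,C14orf177,SLC25A29
ARL13B	1	4	MINA,CRYBG3,ARL6,DHFRL1
ARMC4	3	3	ARHGAP21,OTUD1,PIP4K2A
ATP8A2	1	3	C1QTNF9B-AS1,WASF3,SACS
ATXN10	9	9	TTLL12,RIBC2,SMC1B,GGA1,KCNH3,PIK3R2,KIAA0930,SAMM50,CERK
B9D1	7	3	TNFRSF13B,USP22,GIT1
B9D2	2	7	PLEKHG2,YIF1B,CCDC97,CNFN,CEACAM21,ZNF574,CNTD2
BBIP1	0	0	None
BBS1	13	6	ACTN3,BAK1,BAD,ATP6AP2,PEPD,POLR2G
BBS2	11	10	APOC2,WRNIP1,CETP,GOT2,SPTSSA,CES1,CNOT1,HSF4,MAP2K5,KCNK17
BBS4	13	5	ANP32A,AAGAB,MRPL28,SEMA7A,IGDCC3
BBS5	5	11	SLC6A15,CCDC173,KLHL41,CTSK,COTL1,EIF4EBP3,UBR3,KLHL23,ORM2,PRDM2,HRH1
BBS7	5	8	ANXA5,PDE8B,MSH6,MAD2L1,TRPC3,NDNF,QRFPR,CNGA1
BBS9	0	6	NME8,CD33,EHMT2,TRGV9,FGF2,CAPN1
CASC1	1	2	GOLT1B,PYROXD1
CBY1	8	3	APOL2,BCR,SPTLC3
CC2D2A	0	3	CPEB2,NCAPG,RAB28
CCDC114	8	4	CGB8,EXOC3L2,CGB7,CGB1
CCDC135	6	0	None
CCDC39	0	1	TTC14
CCDC40	1	3	NARF,RPTOR,WDR45B
CCDC63	0	2	ALKBH2,C12orf76
CCDC65	0	3	FAM186B,DNAJC22,RHEBL1
CCNA1	32	7	VDR,RFC3,GJB2,ZNF385A,PSMB9,SLC7A1,EDEM1
CDK3	17	10	CCDC47,CA4,ALG1,TLK2,ITIH4,PRKCA,PECAM1,NAP1L1,FOXJ1,TBX2
CEP290	2	0	None
CETN1	4	10	ALDH7A1,CCNH,GABRE,MUL1,YES1,LGALS3,PTPRM,USP14,TPD52L2,PTAFR
CETN2	9	12	ATP6AP1,C14orf166,ATP2B3,NUCB1,DKC1,PTPRN,CLIC2,DNASE1L1,TEX28,IL2RG,DDX3X,CORIN
CETN3	6	11	ATP6AP1L,HSP90AB1,HOXD10,SGOL1,FABP4,HAPLN1,TNNT1,P3H1,DNAJC19,POLR3G,PRKD3
CHMP5	14	6	NUP98,UBAP1,DYNLL2,TMEM8B,DOPEY2,GPX3
DAW1	2	1	RAB25
DDI2	0	3	AADACL3,CELA2A,PRAMEF1
DNAAF1	0	2	LINC00311,KCNG4
DNAAF2	1	4	ATL1,TRIM9,L2HGDH,TMX1
DNAAF3	0	7	ACPT,BRSK1,SIGLEC14,SIGLEC12,LENG9,LILRA5,ZNF606
DNAH1	0	7	ABHD14A,SEPSECS,LIN7B,POC1A,RPP30,GNL3,G3BP1
DNAH10	0	3	GATC,RILPL2,TMEM120B
DNAH11	0	3	CPVL,GGCT,IL6
DNAH12	0	1	PDE12
DNAH14	1	6	ACBD3,CNIH3,ENAH,TMEM63A,SDE2,MIXL1
DNAH17	0	0	None
DNAH2	0	6	CDK18,CCDC42,KCTD11,ODF4,PIK3R6,KRBA2
DNAH3	0	7	ERI2,TCIRG1,SOD1,THUMPD1,NPIPB3,LOC81691,IVL
DNAH5	0	13	CTNND2,CKB,CDH6,DAP,LARGE,MYO10,TLE1,MVP,RAN,TRIO,MARCH6,MICAL1,RBFOX2
DNAH6	0	1	PLGLB1
DNAH7	2	9	CSTF3,SHC1,STK17B,STAT4,METTL21A,TMEFF2,NABP1,TMEM194B,MIB2
DNAH8	0	3	TOMM6,RAB44,RASGRP1
DNAH9	0	3	YBX2,NLGN2,STX8
DNAI1	2	6	ATG10,CDKN2A,ZIC3,NPR2,METTL21B,GLDC
DNAI2	0	1	MFSD11
DNAJB1	28	10	CYP4F3,ARR3,CEP72,ADGRL3,ELAVL3,DNM2,ILF3,LYL1,SH3BP1,SSTR2
DNAJB13	0	4	BDKRB1,ARFRP1,KLHL35,WISP1
DNAL1	0	3	CIPC,LIN52,SLIRP
DNAL4	9	9	DDX17,CACNA1I,UBA7,TRIOBP,TOM1,GTPBP1,RHOT2,JOSD1,HMGXB4
DNALI1	5	3	GJA4,GJB5,TMEM200B
DRC1	1	4	C2orf44,CENPO,C2orf16,TCF23
DRC7	6	8	CCDC102A,ADGRG5,CPNE2,C16orf70,ZNF319,USB1,NDUFB9,MT4
DRD1	11	5	AP3M1,PLCD1,RARS,PPP4C,KCNMB1
DRD2	20	13	CASP1,CCNA2,CD3G,CD3E,GPC6,SGSH,VWA5A,INPPL1,IL10RA,PSG7,NQO2,RBM22,E2F6
DRD5	5	2	NKX3-2,FGFBP2
DYNLL1	76	5	RFC5,SUDS3,GABRQ,WSB2,VSIG10
DYNLL2	47	9	C17orf67,CHMP5,C17orf47,HSF5,STXBP4,F13A1,KIF2B,PRKD3,MSI2
DYNLRB1	6	2	CBFB,PDRG1
DYNLRB2	4	8	WWOX,SDR42E1,TGFBI,ZNF134,SLC38A8,NECAB2,IRF2BPL,MPHOSPH6
DYNLT1	28	7	CRHBP,ACAT2,SYNJ2,RPS6KA2,TMEM143,PARK2,ERO1L
DYNLT3	7	4	CYBB,IFITM1,UIMC1,FOS
DYX1C1	4	3	GCOM1,PRTG,WDR72
DZIP1L	4	3	PRR23B,NME9,PRR23C
EFHC1	6	2	CENPQ,ADGRF4
ESYT3	0	2	FAIM,SLC35G2
GALR2	1	1	EIF4A3
GALR3	0	4	EIF3D,CEP72,ENTHD1,SUV420H1
GAS8	0	7	FANCA,COX7B,DPEP1,MYLIP,MVD,MC1R,TAF1C
GPR161	0	3	C1orf112,TOR1AIP1,TBX19
GPR83	0	12	FUT4,CST1,CDK2AP1,AQP3,FGF13,PLSCR3,TYR,TPBG,JRKL,MRE11A,NINJ1,SPR
HEPH	0	1	MSN
HSPB11	2	4	C1orf168,C1orf87,RPS26P15,PARS2
HYDIN	1	2	FAM96B,CFDP1
IFT122	1	2	ZNF148,SLCO2A1
IFT140	4	7	DNAJA3,ZNF263,SLC9A3R2,RAB11FIP3,TELO2,IL32,TRAP1
IFT172	2	4	EFR3B,DNAJC27,RAB10,TMEM214
IFT20	28	7	ABHD15,COASY,HLCS,RALGPS2,RICTOR,TP53I13,RAB11FIP4
IFT22	0	5	C7orf43,NFE4,ORAI2,KMT2E,ZNF655
IFT27	2	5	DDX17,TNRC6B,KDELR3,TRIOBP,TAB1
IFT43	2	3	ELMSAN1,LIN52,NEK9
IFT46	0	6	NLRX1,TMPRSS4,SCN3B,TRAPPC4,SIDT2,PDZD3
IFT52	1	2	SPINT3,TOMM34
IFT57	4	6	CLTA,CASP8,CBLB,HTT,SLC25A3,TERT
IFT74	0	0	None
IFT80	1	5	FGFR4,OTOL1,SLITRK3,NMD3,ZBBX
IFT81	1	6	ERP29,NAA25,TPCN1,SLC8B1,SDS,RPH3A
IFT88	6	6	C1QTNF9B-AS1,ALDH8A1,MAP4K5,PDX1,TRIM24,SAP18
INVS	5	2	ABCA1,TMEM245
IQCB1	1	6	CD80,UPK1B,TRH,LMOD1,PVRL3,TBL1X
LCA5	3	1	FILIP1
LOXHD1	0	4	HDHD2,HAUS1,C18orf25,SKA1
LRRC48	0	10	ELAC2,GID4,EIF3E,FUNDC2,SMCR8,ZNF287,SPECC1,PLAGL1,ZNF624,SOD2
LRRC56	0	2	KRTAP5-1,MOB2
LRRC6	2	1	ST3GAL1
MCHR1	2	8	GRAP2,EP300,APOBEC3A,MASP2,EFCAB6,TCIRG1,MRPS18A,ST13
MKS1	2	5	ABCC3,DGKE,CACNA1G,RNF43,SMG8
NEK8	4	0	None
NME5	2	8	HBEGF,APTX,MKRN1,IFITM1,VDAC1,SPOCK1,VIPR1,P4HA2
NME8	1	2	BBS9,SUGCT
NPHP1	15	2	BCL2L11,COX5B
NPHP3	2	15	CCDC50,ANAPC13,COL7A1,ASTE1,NAA50,DPP7,EPC1,DDX3Y,CDV3,DNAJC13,PIK3R4,TOPBP1,PARP14,PPP2R3A,RAB6B
NPHP4	1	6	FBXO44,EDIL3,C1orf127,TMEM201,SCRG1,RBP7
NPY2R	4	3	APOC3,ABCE1,SMAD1
NPY5R	4	2	MDH2,KIF23
PDCD6IP	37	5	ATG7,CLASP2,FBXL2,CRTAP,STAC
PIH1D1	31	5	CABP5,C19orf73,RCN3,RASIP1,PRKG2
PKD1	24	9	NTHL1,NADSYN1,PDPK1,OR1F1,DDX58,NTN3,RPL3L,SOX17,PPL
PKD1L1	0	10	C7orf69,ABCC3,C7orf65,ACAA2,C7orf57,MGAT2,ABCA13,RPL6,PLCB2,PSME3
PKD2	14	6	KIF11,ADH1C,MTAP,ADH1A,PPP3CA,UCHL3
PKD2L1	3	6	MYOF,HNRNPA2B1,LGI1,CAB39,GBF1,PRPS2
PKHD1	1	7	ORM1,CSTF2T,ILK,ATXN2,EML4,BAG2,PTGIS
PPIL6	0	2	AK9,CEP57L1
PPP1CB	26	9	NRBP1,DHX57,GCKR,NCOA1,MATN1,SRD5A2,UPK2,SH3KBP1,ZNF512
PTCH1	65	5	CORO2A,ECM2,DPP3,TMOD1,UFM1
QRFPR	0	9	BBS12,BBS7,NDNF,EXOSC9,ADAD1,KIAA1109,TRPC3,TNIP3,TMEM155
RABL5	0	0	None
ROPN1L	3	4	FAM173B,42435,CMBL,CCT5
RPGR	11	5	NUDT12,ATP6AP2,USP9X,SLC9A7,TSPAN7
RPGRIP1	23	1	SLC6A2
RPGRIP1L	3	2	CES1P1,SLC6A2
RSPH1	1	7	LINC01547,OSMR,COL18A1,LINC00313,LINC00334,LRRC3,UMODL1
RSPH10B	0	7	DAGLB,CCZ1B,FOXK1,MMD2,RBAKDN,GRID2IP,SLC29A4
RSPH3	5	6	PNLDC1,MRPL18,RGS17,TAGAP,SERAC1,SYTL3
RSPH4A	0	6	LACE1,HS3ST5,FAM26F,FLJ34503,FAM26E,ZUFSP
RSPH6A	0	1	SLC1A5
RSPH9	2	9	C6orf223,LRRC73,OARD1,KLHDC3,ADCY10P1,TSPO2,TCTE1,TAF8,SPATS1
RTDR1	13	0	None
SMO	8	1	LINC-PINT
SPAG1	3	7	MME,NIPAL2,CPQ,POLR2K,RGS22,COL4A1,STK3
SPAG16	2	1	IKZF2
SPAG17	0	2	GDAP2,FAM46C
SPAG6	2	2	OTUD1,PIP4K2A
SPEF2	0	10	C5orf42,BRIX1,NIPBL,LMBRD2,DNAJC21,CAPSL,NADK2,UGT3A1,TARS,WDR70
TCTE1	1	7	KLC4,C6orf223,LRRC73,KLHDC3,SPATS1,TAF8,RSPH9
TCTE3	1	4	TCP10,LINC01558,RPS6KA2,RNASET2
TCTN1	0	3	GLTP,SVOP,FAM222A
TCTN2	0	3	COQ5,KDM2B,CCDC92
TCTN3	0	0	None
TMEM17	0	3	FAM161A,COMMD1,C2orf74
TMEM216	1	9	TEX40,SAC3D1,ATL3,EFEMP2,CABP2,CCDC87,SSH3,POLA2,TRMT112
TMEM231	3	4	TMEM170A,CNTNAP4,ADAT1,VAT1L
TMEM237	2	2	ATP6V1C2,SFXN5
TMEM30B	0	4	BCAR1,SLC38A6,C14orf37,NAA30
TMEM67	1	4	NDUFAF6,INTS8,FAM92A1,LAPTM4B
TRAF3IP1	27	3	ATG4B,ANO7,SNED1
TSG101	86	10	PILRA,RPS13,MYLPF,DNAJB11,CALML5,ST5,PPP2R5D,MAPK15,ZNF160,ZNF419
TTC21B	0	4	COBLL1,G6PC2,CSRNP3,CERS6
TTC28	3	4	GATSL3,TPST2,PES1,PITPNB
TTC30B	0	7	FKBP7,CCDC141,PLEKHA3,RBM45,HNRNPA3,SESTD1,TTC30A
TTC8	1	1	PTPN21
VPS28	27	7	THEM6,CCNB1,OXCT1,OPLAH,RPL37A,SCRIB,CACNA1I
VPS37A	7	4	MICU3,CCAR2,COL11A2,KIAA1456
VPS4B	7	2	SPHAR,PHLPP1
WDR19	0	3	NWD2,TLR10,CHRNA9
WDR35	0	0	None
WDR63	0	2	RPL17P5,RPF1
WDR78	0	1	GNG12
ZMYND10	10	2	ACTR3,RALGDS
ZMYND12	0	3	ERMAP,C1orf50,CABIN1
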