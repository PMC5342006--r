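feature	marker1	marker2	pSingle1	pSingle2	pPair	qPair	logrankPair
survival3y	FEN1(N)	RAD54B(N)	0.357	0.002	0.001	0.126	0.000
survival3y	BRCA1(C)	RAD54B(N)	0.442	0.002	0.001	0.126	0.000
survival3y	PARP1(N)	RAD54B(N)	0.252	0.002	0.002	0.162	0.000
survival3y	BRCA1(C)	FEN1(N)	0.442	0.357	0.016	0.356	0.056
metastasis	CSNK1E(C)	TP53(N)	0.682	0.012	0.003	0.369	0.420
metastasis	BRCA1(C)	TP53(N)	0.281	0.012	0.005	0.369	0.129
metastasis	POLB(N)	TP53(N)	0.485	0.012	0.007	0.369	0.108
metastasis	PARP1(N)	TP53(N)	0.299	0.012	0.008	0.369	0.414
metastasis	RB1(N)	TP53(N)	0.114	0.012	0.008	0.369	0.092
metastasis	BRCA1(C)	RB1(N)	0.281	0.114	0.037	0.897	0.756
nodal	CDH1(M)	MSH2(C)	0.472	0.084	0.007	0.973	0.280
nodal	BRCA2(C)	MSH2(C)	0.245	0.084	0.016	0.973	0.520
nodal	FEN1(N)	MSH2(C)	0.212	0.084	0.022	0.973	0.502
nodal	BRCA1(C)	EGFR(C)	0.355	0.103	0.033	0.973	0.857
nodal	BRCA2(N)	TP53(N)	0.190	0.351	0.045	0.973	0.483
nodal	MSH2(C)	RB1(N)	0.084	0.220	0.045	0.973	0.306
grade	ABL1(C)	CTNNB1(N)	0.781	0.169	0.021	0.931	0.842
grade	ARK2(C)	BRCA2(N)	0.380	0.108	0.031	0.931	0.720
grade	BRCA2(N)	POLB(N)	0.108	0.384	0.039	0.931	0.985
grade	MSH2(C)	MYC(N)	0.058	0.448	0.047	0.931	0.347
grade	BRCA1(C)	BRCA2(N)	0.407	0.108	0.049	0.931	0.338
stage	CDH1(M)	RB1(N)	0.346	0.107	0.012	0.974	0.632
stage	EGFR(C)	RB1(N)	0.268	0.107	0.031	0.974	0.882
stage	FEN1(N)	MSH2(C)	0.538	0.395	0.033	0.974	0.502
stage	BRCA1(C)	TP53(N)	0.217	0.144	0.038	0.974	0.129
stage	PARP1(N)	RB1(N)	0.381	0.107	0.048	0.974	0.234
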