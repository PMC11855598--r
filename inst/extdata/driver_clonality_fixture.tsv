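patient	gene	population	effect	clonality
1	KIT	1PST1	non_synonymous	clonal
1	KIT	1PST2	non_synonymous	clonal
1	KIT	1MT1	non_synonymous	clonal
1	KIT	1MT2	non_synonymous	clonal
1	MECOM	1PST1	non_synonymous	clonal
1	MECOM	1PST2	non_synonymous	clonal
1	MECOM	1MT1	non_synonymous	clonal
1	MECOM	1MT2	non_synonymous	clonal
1	NRAS	1PST1	non_synonymous	clonal
1	NRAS	1PST2	non_synonymous	clonal
1	NRAS	1MT1	non_synonymous	clonal
1	NRAS	1MT2	non_synonymous	clonal
1	KMT2D	1PST1	non_synonymous	clonal
1	KMT2D	1PST2	non_synonymous	clonal
1	KMT2D	1MT1	non_synonymous	clonal
1	KMT2D	1MT2	non_synonymous	clonal
1	TP53	1PST1	non_synonymous	clonal
1	TP53	1PST2	non_synonymous	clonal
1	TP53	1MT1	non_synonymous	clonal
1	TP53	1MT2	non_synonymous	clonal
1	COL5A1	1PST1	non_synonymous	clonal
1	COL5A1	1PST2	non_synonymous	clonal
1	COL5A1	1MT1	non_synonymous	subclonal
1	CTNNB1	1MT2	non_synonymous	subclonal
2	NRAS	2PST	non_synonymous	clonal
2	NRAS	2MT	non_synonymous	clonal
2	KMT2D	2PST	non_synonymous	clonal
2	KMT2D	2MT	non_synonymous	clonal
2	NF1	2PST	non_synonymous	clonal
2	NF1	2MT	non_synonymous	clonal
2	ARID2	2PST	non_synonymous	clonal
2	ARID2	2MT	non_synonymous	clonal
2	COL5A1	2PST	non_synonymous	clonal
2	COL5A1	2MT	non_synonymous	subclonal
3	BRAF	3PST	non_synonymous	clonal
3	BRAF	3MT	non_synonymous	clonal
3	PPP6C	3PST	non_synonymous	subclonal
3	PPP6C	3MT	non_synonymous	clonal
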