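patient	biopsy	population	ploidy_facs	purity_presort_pct	purity_postsort_pct
1	primary_site	1PST1	1.7	19	88
1	primary_site	1PST2	2.7	41	95
1	skin_metastasis	1MT1	2.6	80	91
1	lymph_node_metastasis	1MT2	2.7	40	93
2	primary_site	2PST	1.9	80	88
2	lymph_node_metastasis	2MT	1.9	88	96
3	primary_site	3PST	3.0	87	91
3	breast_metastasis	3MT	3.1	78	87
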