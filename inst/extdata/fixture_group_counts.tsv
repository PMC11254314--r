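# per-group integration counts at full study scale (differential-metabolite
# totals and joint/relation pathway counts), as inputs to the correlation
# analysis
dose	time	group	n_differential_metabolites	n_joint_pathways	n_relation_pathways
100	12	100uM-12h	51	4	2
100	24	100uM-24h	48	2	1
100	48	100uM-48h	27	0	0
200	12	200uM-12h	48	4	4
200	24	200uM-24h	66	2	0
200	48	200uM-48h	60	2	2
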