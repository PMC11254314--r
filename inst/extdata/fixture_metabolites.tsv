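# differential metabolites per treatment group
id	kind	dose_uM	time_h	direction
Uric acid	metabolite	100	12	up
Palmitic acid	metabolite	100	12	up
Oleic acid	metabolite	100	12	up
Linoleic acid	metabolite	100	12	down
L-Glutamate	metabolite	100	12	down
3-Sulfinylpyruvate	metabolite	100	24	down
L-Glutamate	metabolite	100	24	down
L-Lactate	metabolite	100	48	up
Citrate	metabolite	100	48	down
dGMP	metabolite	200	12	down
Uridine	metabolite	200	12	down
dUMP	metabolite	200	12	up
D-Glucose 1-phosphate	metabolite	200	12	up
Bilirubin	metabolite	200	12	down
L-Glutamate	metabolite	200	24	up
Taurine	metabolite	200	24	up
5'-Methylthioadenosine	metabolite	200	48	up
L-Cystathionine	metabolite	200	48	up
sn-Glycero-3-phosphocholine	metabolite	200	48	up
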