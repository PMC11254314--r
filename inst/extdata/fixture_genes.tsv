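# differential genes per treatment group (dose uM, time h)
id	kind	dose_uM	time_h	direction
Rrm2	gene	100	12	up
Acot2	gene	100	12	down
Gclc	gene	100	12	up
Ass1	gene	100	12	down
Cat	gene	100	12	up
Mat2a	gene	100	24	down
Gclc	gene	100	24	down
Tfrc	gene	100	24	up
Sod2	gene	100	48	up
Rrm2	gene	200	12	up
Gnpnat1	gene	200	12	down
Cp	gene	200	12	down
Gclc	gene	200	24	up
Ass1	gene	200	24	down
Mat2a	gene	200	48	down
Gpd1	gene	200	48	down
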