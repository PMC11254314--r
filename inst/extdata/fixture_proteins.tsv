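# differential proteins per treatment group; CAT direction contradicts its
# gene, so Cat/CAT is not a consistent pair
id	kind	dose_uM	time_h	direction
RRM2	protein	100	12	up
ACOT2	protein	100	12	down
GCLC	protein	100	12	up
ASS1	protein	100	12	down
CAT	protein	100	12	down
MAT2A	protein	100	24	down
GCLC	protein	100	24	down
SOD2	protein	100	48	up
RRM2	protein	200	12	up
GNPNAT1	protein	200	12	down
CP	protein	200	12	down
GCLC	protein	200	24	up
ASS1	protein	200	24	down
MAT2A	protein	200	48	down
GPD1	protein	200	48	down
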