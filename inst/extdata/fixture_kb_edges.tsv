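pathway_id	source	target	catalyst_genes
purine	gdp	dgdp	Rrm2
purine	dgdp	dgmp	
purine	dgmp	guanosine	
purine	guanosine	guanine	
purine	guanine	xanthine	
purine	xanthine	uric acid	
unsat_fa	palmitoyl-coa	palmitic acid	Acot2
unsat_fa	palmitic acid	stearic acid	
unsat_fa	stearic acid	oleic acid	
unsat_fa	oleic acid	linoleic acid	
cys_met	methionine	s-adenosylmethionine	Mat2a
cys_met	s-adenosylmethionine	5'-methylthioadenosine	
cys_met	s-adenosylmethionine	s-adenosylhomocysteine	
cys_met	s-adenosylhomocysteine	homocysteine	
cys_met	homocysteine	l-cystathionine	
cys_met	l-cystathionine	l-cysteine	
cys_met	l-cysteine	3-sulfinylpyruvate	
pyrimidine	udp	dudp	Rrm2
pyrimidine	dudp	dump	
pyrimidine	dump	deoxyuridine	
pyrimidine	deoxyuridine	uracil	
pyrimidine	uracil	uridine	
amino_sugar	glucosamine 6-phosphate	n-acetylglucosamine 6-phosphate	Gnpnat1
amino_sugar	n-acetylglucosamine 6-phosphate	n-acetylglucosamine 1-phosphate	
amino_sugar	n-acetylglucosamine 1-phosphate	d-glucose 1-phosphate	
porphyrin	protoporphyrin ix	heme	Cp
porphyrin	heme	biliverdin	
porphyrin	biliverdin	bilirubin	
glycerophospholipid	dihydroxyacetone phosphate	sn-glycerol 3-phosphate	Gpd1
glycerophospholipid	sn-glycerol 3-phosphate	phosphatidylcholine	
glycerophospholipid	phosphatidylcholine	sn-glycero-3-phosphocholine	
glutathione	l-glutamate	gamma-glutamylcysteine	Gclc
glutathione	gamma-glutamylcysteine	glutathione	
arginine_biosyn	l-citrulline	l-argininosuccinate	Ass1
arginine_biosyn	l-argininosuccinate	l-arginine	
tca	citrate	isocitrate	
tca	isocitrate	2-oxoglutarate	Idh1
galactose	d-galactose	galactose 1-phosphate	Galk1
tryptophan	l-tryptophan	n-formylkynurenine	Tdo2
tryptophan	n-formylkynurenine	l-kynurenine	
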