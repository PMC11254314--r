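purine	Purine metabolism	g:Rrm2	m:gdp	m:dgdp	m:dgmp	m:guanosine	m:guanine	m:xanthine	m:uric acid
unsat_fa	Biosynthesis of unsaturated fatty acids	g:Acot2	m:palmitoyl-coa	m:palmitic acid	m:stearic acid	m:oleic acid	m:linoleic acid
cys_met	Cysteine and methionine metabolism	g:Mat2a	m:methionine	m:s-adenosylmethionine	m:5'-methylthioadenosine	m:s-adenosylhomocysteine	m:homocysteine	m:l-cystathionine	m:l-cysteine	m:3-sulfinylpyruvate
pyrimidine	Pyrimidine metabolism	g:Rrm2	m:udp	m:dudp	m:dump	m:deoxyuridine	m:uracil	m:uridine
amino_sugar	Amino sugar and nucleotide sugar metabolism	g:Gnpnat1	m:glucosamine 6-phosphate	m:n-acetylglucosamine 6-phosphate	m:n-acetylglucosamine 1-phosphate	m:d-glucose 1-phosphate
porphyrin	Porphyrin metabolism	g:Cp	m:protoporphyrin ix	m:heme	m:biliverdin	m:bilirubin
glycerophospholipid	Glycerophospholipid metabolism	g:Gpd1	m:dihydroxyacetone phosphate	m:sn-glycerol 3-phosphate	m:phosphatidylcholine	m:sn-glycero-3-phosphocholine
glutathione	Glutathione metabolism	g:Gclc	m:l-glutamate	m:gamma-glutamylcysteine	m:glutathione
arginine_biosyn	Arginine biosynthesis	g:Ass1	m:l-glutamate	m:l-citrulline	m:l-argininosuccinate	m:l-arginine
tca	Citrate cycle	g:Idh1	m:citrate	m:isocitrate	m:2-oxoglutarate
galactose	Galactose metabolism	g:Galk1	m:d-galactose	m:galactose 1-phosphate
tryptophan	Tryptophan metabolism	g:Tdo2	m:l-tryptophan	m:n-formylkynurenine	m:l-kynurenine
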