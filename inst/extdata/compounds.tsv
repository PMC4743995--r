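compound_id	name	formula	logp	organism_ids	is_osmoprotectant
glu	L-glutamate	C5H9NO4	-3.69		TRUE
pro	L-proline	C5H9NO2	-2.54		TRUE
tre	trehalose	C12H22O11	-4.23		TRUE
bet	glycine betaine	C5H11NO2	-4.93		TRUE
tau	taurine	C2H7NO3S	-4.28		TRUE
htau	hypotaurine	C2H7NO2S	-3.95		TRUE
sor	D-sorbitol	C6H14O6	-2.20		TRUE
mtl	D-mannitol	C6H14O6	-2.23		TRUE
ino	myo-inositol	C6H12O6	-2.08		TRUE
ect	ectoine	C6H10N2O2	-3.50	eco;bsu;mcf7;hdf	TRUE
gol	glycerol	C3H8O3	-1.76		TRUE
gly	glycine	C2H5NO2	-3.21		TRUE
urea	urea	CH4N2O	-2.11		TRUE
dmg	N,N-dimethylglycine	C4H9NO2	-3.20		TRUE
naorn	N-acetylornithine	C7H14N2O3	-3.02		TRUE
naasp	N-acetyl-L-aspartate	C6H9NO5	-2.50		TRUE
arg	L-arginine	C6H14N4O2	-4.20		TRUE
mal	L-malate	C4H6O5	-1.26		TRUE
gsh	glutathione	C10H17N3O6S	-4.50		TRUE
gssg	glutathione disulfide	C20H32N6O12S2	-7.00		TRUE
dha	dehydroascorbate	C6H6O6	-1.70		TRUE
q8	ubiquinone-8	C49H74O4	10.20	eco;pfl;ppu;zmo;rsp;sme;atu;pve	TRUE
q10	ubiquinone-10	C59H90O4	12.10	rsp;sce;spo;mcf7;hdf	TRUE
val	L-valine	C5H11NO2	-2.26		FALSE
leu	L-leucine	C6H13NO2	-1.52		FALSE
ile	L-isoleucine	C6H13NO2	-1.70		FALSE
phe	L-phenylalanine	C9H11NO2	-1.38		FALSE
trp	L-tryptophan	C11H12N2O2	-1.05		FALSE
met	L-methionine	C5H11NO2S	-1.87		FALSE
thr	L-threonine	C4H9NO3	-2.94		FALSE
lys	L-lysine	C6H14N2O2	-3.05		FALSE
his	L-histidine	C6H9N3O2	-3.32		FALSE
ser	L-serine	C3H7NO3	-3.07		FALSE
ala	L-alanine	C3H7NO2	-2.85		FALSE
pyr	pyruvate	C3H4O3	-1.24		FALSE
akg	2-oxoglutarate	C5H6O5	-1.93		FALSE
cit	citrate	C6H8O7	-1.64		FALSE
fum	fumarate	C4H4O4	-0.78		FALSE
suc	succinate	C4H6O4	-0.59		FALSE
hex	hexose	C6H12O6	-2.60		FALSE
g6p	glucose 6-phosphate	C6H13O9P	-4.00		FALSE
f6p	fructose 6-phosphate	C6H13O9P	-3.90		FALSE
pep	phosphoenolpyruvate	C3H5O6P	-1.30		FALSE
pg3	3-phosphoglycerate	C3H7O7P	-2.50		FALSE
cyt	cytosine	C4H5N3O	-1.73		FALSE
coa	coenzyme A	C21H36N7O16P3S	-5.60		FALSE
ala5	5-aminolevulinate	C5H9NO3	-2.90		FALSE
pbg	porphobilinogen	C10H14N2O4	-2.50		FALSE
pam	palmitate	C16H32O2	6.40		FALSE
ole	oleate	C18H34O2	7.00		FALSE
chol	cholesterol	C27H46O	8.70	mcf7;hdf	FALSE
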