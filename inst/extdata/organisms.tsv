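organism_id	display_name	taxonomy_group	habitat	cell_wall	ic10	ic25	ic50	n_bio_replicates
eco	Escherichia coli	gamma-proteobacteria	animal-associated	thin	NA	NA	NA	4
pfl	Pseudomonas fluorescens	gamma-proteobacteria	plant-associated	thin	NA	NA	NA	4
ppu	Pseudomonas putida	gamma-proteobacteria	free-living	thin	NA	NA	NA	4
zmo	Zymomonas mobilis	alpha-proteobacteria	plant-associated	thin	NA	NA	1500	4
rsp	Rhodobacter sphaeroides	alpha-proteobacteria	free-living	thin	NA	NA	NA	4
sme	Sinorhizobium meliloti	alpha-proteobacteria	plant-associated	thin	NA	NA	NA	4
atu	Agrobacterium tumefaciens	alpha-proteobacteria	plant-associated	thin	NA	NA	NA	4
pve	Paracoccus versutus	alpha-proteobacteria	free-living	thin	NA	NA	NA	4
bsu	Bacillus subtilis	firmicutes	free-living	thick	NA	NA	NA	4
lca	Lacticaseibacillus casei	firmicutes	animal-associated	thick	NA	NA	NA	4
cgl	Corynebacterium glutamicum	actinobacteria	free-living	thick	NA	NA	NA	4
msm	Mycobacterium smegmatis	actinobacteria	free-living	thick	NA	NA	NA	4
sce	Saccharomyces cerevisiae	fungi	plant-associated	thick	NA	NA	NA	4
spo	Schizosaccharomyces pombe	fungi	plant-associated	thick	NA	NA	NA	4
mcf7	Homo sapiens MCF7	human	animal-associated	none	NA	NA	150	3
hdf	Homo sapiens HDF	human	animal-associated	none	NA	NA	NA	3
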