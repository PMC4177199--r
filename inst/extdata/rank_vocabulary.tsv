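canonical_name	level	aliases
domain	4	superkingdom
kingdom	8	
subkingdom	10	
superphylum	12	
phylum	14	division
subphylum	16	subdivision
infraphylum	18	
superclass	20	
class	22	
subclass	24	
infraclass	26	
cohort	28	
subcohort	30	
superorder	32	
order	34	
suborder	36	
infraorder	38	
parvorder	40	
superfamily	44	
family	46	
subfamily	48	
tribe	50	
subtribe	52	
genus	56	
subgenus	58	
species group	60	
species subgroup	62	
species	66	
subspecies	70	
varietas	NA	variety
forma	NA	form
section	NA	
series	NA	
morph	NA	
pathogroup	NA	
serogroup	NA	
serotype	NA	
strain	NA	
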