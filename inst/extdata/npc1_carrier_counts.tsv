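group	het	hom	het_male	hom_male	specific_mutations	specific_mutated_alleles	specific_het	specific_hom
afr	265	0	96	0	32	44	44	0
asj	28	0	8	0	5	7	7	0
eas	107	0	48	0	36	46	46	0
eur	548	0	296	0	167	275	275	0
lat	251	0	106	0	43	107	107	0
sas	367	4	259	3	57	132	130	1
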