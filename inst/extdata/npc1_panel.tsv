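label	n	n_male	n_female	other
afr	8128	3093	5035	0
asj	5040	2590	2450	0
eas	9197	4533	4664	0
eur	67709	37442	30267	0
lat	17296	7161	10135	0
sas	15308	11536	3772	0
oth	3070	1577	1493	1
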