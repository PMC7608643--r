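# protein_length=1278
# SYNTHETIC domain model of the NPC1 protein (isoform 1, 1278 aa).
# Exact published boundary coordinates are not available in text form;
# these intervals are constructed to honour the alternating luminal /
# transmembrane / cytoplasmic topology (27 domains, SSD = TD3-TD7) and
# every domain length that published burden percentages pin down
# (LDC=248, CDJ=14, CDL=29, CDN=30, TD4=20, TD7=20). Other boundaries
# are approximate. Residues outside every interval are linker.
name	category	start	end	in_ssd
LDA	luminal	25	264	0
TD1	transmembrane	265	285	0
CDB	cytoplasmic	286	350	0
TD2	transmembrane	351	371	0
LDC	luminal	373	620	0
TD3	transmembrane	621	641	1
CDD	cytoplasmic	642	655	0
TD4	transmembrane	656	675	1
LDE	luminal	676	710	0
TD5	transmembrane	711	731	1
CDF	cytoplasmic	732	745	0
TD6	transmembrane	746	766	1
LDG	luminal	767	780	0
TD7	transmembrane	781	800	1
CDH	cytoplasmic	801	830	0
TD8	transmembrane	831	851	0
LDI	luminal	855	1098	0
TD9	transmembrane	1099	1119	0
CDJ	cytoplasmic	1120	1133	0
TD10	transmembrane	1134	1154	0
LDK	luminal	1155	1163	0
TD11	transmembrane	1164	1184	0
CDL	cytoplasmic	1185	1213	0
TD12	transmembrane	1214	1234	0
LDM	luminal	1235	1240	0
TD13	transmembrane	1241	1248	0
CDN	cytoplasmic	1249	1278	0
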