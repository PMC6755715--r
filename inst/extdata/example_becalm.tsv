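1	A	0	9	0.54488	α-maltose	compounds	http://purl.obolibrary.org/obo/CHEBI_18167
1	A	14	28	0.62108	nicotinic acid	compounds	http://purl.obolibrary.org/obo/CHEBI_15940
1	A	14	45	0.70879	nicotinic acid D-ribonucleotide	compounds	http://purl.obolibrary.org/obo/CHEBI_15763
1	A	65	79	0.62108	nicotinic acid	compounds	http://purl.obolibrary.org/obo/CHEBI_15940
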