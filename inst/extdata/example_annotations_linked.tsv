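0	9	α-maltose	http://purl.obolibrary.org/obo/CHEBI_18167
14	28	nicotinic acid	http://purl.obolibrary.org/obo/CHEBI_15940
14	45	nicotinic acid D-ribonucleotide	http://purl.obolibrary.org/obo/CHEBI_15763
65	79	nicotinic acid	http://purl.obolibrary.org/obo/CHEBI_15940
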