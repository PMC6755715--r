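α-maltose	http://purl.obolibrary.org/obo/CHEBI_18167
nicotinic acid	http://purl.obolibrary.org/obo/CHEBI_15940
nicotinic acid D-ribonucleotide	http://purl.obolibrary.org/obo/CHEBI_15763
nicotinic acid-adenine dinucleotide phosphate	http://purl.obolibrary.org/obo/CHEBI_76072
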