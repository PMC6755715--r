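0	9	α-maltose
14	28	nicotinic acid
14	45	nicotinic acid D-ribonucleotide
65	79	nicotinic acid
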