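α-maltose and nicotinic acid D-ribonucleotide was found, but not nicotinic acid
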