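ligand	pic50
CH3	6.9
Cl	7.7
Br	7.9
I	8.2
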