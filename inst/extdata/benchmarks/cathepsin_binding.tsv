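ligand	empirical	short_range	mo_based	whole_fmo	dev_printed_empirical	dev_printed_short_range	dev_printed_mo_based
CH3	-8.8	-65.9	-72.6	-75.2	66.4	9.3	2.6
Cl	-11.4	-79.4	-87.8	-88.6	77.2	9.2	0.8
Br	-14.3	-82.8	-92.0	-90.4	76.0	7.5	-1.6
I	-13.9	-83.6	-95.6	-96.0	82.1	12.4	0.4
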