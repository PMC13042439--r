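component	empirical	short_range	mo_based	whole_fmo
electrostatic	-15.6	-50.9	-61.0	-54.9
exchange_repulsion	-1.7	0.4	0.0	0.0
charge_transfer	-2.0	-3.2	-2.7	-2.0
dispersion	-11.4	-76.1	-84.2	-84.2
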