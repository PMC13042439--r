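model	qm_atoms	ip_eV	ea_eV
empirical	66	9.9	3.5
short_range	366	10.1	3.4
mo_based	1326	10.2	3.2
whole_fmo	3286	10.3	3.2
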