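protein_a	protein_b
E05	E11
E26	E29
E12	E23
E03	E07
E04	E30
E05	E26
E08	E23
E11	E22
E10	E20
E04	E10
E01	E23
E08	E19
E06	E16
E08	E20
E08	E25
E02	E13
E07	E29
E12	E26
E01	E13
E05	E09
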