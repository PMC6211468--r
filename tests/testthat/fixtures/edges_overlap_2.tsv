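protein_a	protein_b
E08	E21
E13	E15
E06	E29
E08	E30
E02	E17
E23	E29
E17	E18
E03	E12
E20	E29
E03	E09
E01	E18
E11	E23
E01	E16
E13	E22
E15	E16
E18	E19
E08	E23
E04	E08
E07	E13
E01	E30
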