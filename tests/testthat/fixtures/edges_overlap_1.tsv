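protein_a	protein_b
E10	E25
E04	E06
E07	E15
E01	E20
E02	E28
E20	E29
E23	E26
E11	E12
E14	E25
E18	E23
E06	E27
E19	E25
E01	E08
E12	E21
E21	E25
E10	E23
E22	E24
E06	E14
E10	E26
E09	E19
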