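id	symbol	source
P1	p1	drugbank
P2	p2	drugbank
P3	p3	drugbank
P1	p1	drugbank
P4	p4	drugbank
P2	p2	drugbank
P5	p5	drugbank
P6	p6	drugbank
P1	p1	drugbank
P7	p7	drugbank
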