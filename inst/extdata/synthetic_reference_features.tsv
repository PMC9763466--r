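# name	start	end	strand
left_flank	1	200	+
ctdna	201	5487	+
left_ir	201	1148	+
acs	642	1840	+
susL	2677	3657	+
rolB	4218	4532	+
right_ir	4528	5487	+
right_flank	5488	5687	+
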