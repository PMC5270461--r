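gene	CycD	Rb	p27	E2F	CycE	CycA	Cdc20	Cdh1	UbcH10	CycB
CycD	1	0	0	0	0	0	0	0	0	0
Rb	-1	0	1	0	-1	-1	0	0	0	-1
p27	-1	0	1	0	-1	-1	0	0	0	-1
E2F	0	-1	1	0	0	-1	0	0	0	-1
CycE	0	-1	1	1	-1	-1	0	0	0	0
CycA	0	-1	0	1	0	1	-1	-1	-1	0
Cdc20	0	0	0	0	0	0	0	-1	0	1
Cdh1	0	0	1	0	0	-1	1	0	0	-1
UbcH10	0	0	0	0	0	1	1	-1	1	1
CycB	0	0	0	0	0	0	-1	-1	0	0
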