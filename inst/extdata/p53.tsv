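gene	DNAdamage	p53	p14ARF	ATR	ATM	CHEK1	CHEK2	MDM2	MDMX
DNAdamage	1	0	0	0	0	0	0	0	0
p53	0	0	0	1	0	1	1	-1	-1
p14ARF	0	0	1	0	0	0	0	0	0
ATR	1	0	0	0	0	0	0	0	0
ATM	1	0	0	0	0	0	0	0	0
CHEK1	0	0	0	1	0	0	0	0	0
CHEK2	0	0	0	0	1	0	0	0	0
MDM2	0	0	-1	0	0	0	0	0	1
MDMX	0	0	0	0	0	0	0	-1	0
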