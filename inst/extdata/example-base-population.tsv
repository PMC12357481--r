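position	bias	haplotype
1500000	0	1
12000000	-50	4
23456789	50	7
34000000	0	10
45000000	-50	13
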