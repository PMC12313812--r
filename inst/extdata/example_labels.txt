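0.000000	0.412000	caw
0.690000	1.034000	caw
1.310000	1.612000	caw
3.950000	4.300000	caw
4.580000	4.870000	caw
7.200000	7.745000	caw
9.100000	9.430000	id:unknown
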