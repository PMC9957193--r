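family	trait	comparison	re
A	GY	plain_vs_C	1.141
A	GY	plain_vs_AC	1.137
A	GY	C_vs_AC	0.996
A	DTF	plain_vs_C	1.169
A	DTF	plain_vs_AC	1.167
A	DTF	C_vs_AC	0.998
A	DTH	plain_vs_C	1.176
A	DTH	plain_vs_AC	1.178
A	DTH	C_vs_AC	1.002
B	GY	plain_vs_C	1.055
B	GY	plain_vs_AC	1.053
B	GY	C_vs_AC	0.998
B	DTF	plain_vs_C	1.119
B	DTF	plain_vs_AC	1.129
B	DTF	C_vs_AC	1.009
B	DTH	plain_vs_C	1.120
B	DTH	plain_vs_AC	1.133
B	DTH	C_vs_AC	1.011
C	GY	plain_vs_C	1.514
C	GY	plain_vs_AC	1.551
C	DTF	plain_vs_C	1.964
C	DTF	plain_vs_AC	1.996
C	DTH	plain_vs_C	1.955
C	DTH	plain_vs_AC	2.005
D	GY	plain_vs_C	1.064
D	GY	plain_vs_AC	1.060
D	DTF	plain_vs_C	1.106
D	DTF	plain_vs_AC	1.113
D	DTH	plain_vs_C	1.112
D	DTH	plain_vs_AC	1.120
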