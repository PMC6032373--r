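atom_type	rstar	epsstar	q
N	1.8240	0.1700	-0.4157
CA	1.9080	0.1094	0.0337
C	1.9080	0.0860	0.5973
O	1.6612	0.2100	-0.5679
CB	1.9080	0.1094	0.0000
OXT	1.6612	0.2100	-0.8055
P	2.1000	0.2000	1.1662
OP1	1.6612	0.2100	-0.7760
OP2	1.6612	0.2100	-0.7760
O5'	1.6837	0.1700	-0.4989
C5'	1.9080	0.1094	0.0558
C4'	1.9080	0.1094	0.1065
O4'	1.6837	0.1700	-0.3548
C3'	1.9080	0.1094	0.2022
O3'	1.6837	0.1700	-0.5246
C2'	1.9080	0.1094	0.0670
O2'	1.7210	0.2104	-0.6139
C1'	1.9080	0.1094	0.0394
N9	1.8240	0.1700	-0.0251
N1	1.8240	0.1700	-0.0484
S	2.0000	0.2500	-0.3119
H	0.6000	0.0157	0.0000
SE	2.1000	0.2500	0.0000
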