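metric	EIF4G1	LRP1	PFN2	RPS18	RPS6	EEF2
ASPL	2.436	1.667	1.500	2.331	2.056	2.667
BC	0.160	0.167	0.167	0.089	0.151	0.333
CC	0.431	0.630	0.695	0.444	0.508	0.392
NC	4.753	4.333	3.100	5.039	4.444	1.857
TC	0.221	0.000	0.400	0.398	0.056	0.357
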