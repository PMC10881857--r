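metric	CAPN2	mir125b-mir199a2	mir199a2	mir125b
ASPL	1.781	1.933	1.50	1.821
BC	0.060	0.117	0.25	0.137
CC	0.580	0.539	0.70	0.573
NC	11.299	5.000	2.50	4.500
TC	0.543	0.255	0.00	0.298
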