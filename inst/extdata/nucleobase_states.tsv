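base	functional	state	E0_ev	f	character
uracil	CAM-B3LYP	S1	5.10	0.000	nOpi*1
uracil	CAM-B3LYP	S2	5.50	0.190	pipi*1
uracil	CAM-B3LYP	S3	6.18	0.003	piRysigma1
uracil	CAM-B3LYP	S5	6.62	0.045	pipi*2
uracil	CAM-B3LYP	S6	6.88	0.170	pipi*3
uracil	PBE0	S1	4.82	0.000	nOpi*1
uracil	PBE0	S2	5.33	0.150	pipi*1
uracil	PBE0	S4	6.05	0.002	piRysigma1
uracil	PBE0	S5	6.14	0.039	pipi*2
uracil	PBE0	S7	6.63	0.130	pipi*3
thymine	CAM-B3LYP	S1	5.14	0.000	nOpi*1
thymine	CAM-B3LYP	S2	5.31	0.192	pipi*1
thymine	CAM-B3LYP	S3	5.94	0.001	piRysigma1
thymine	CAM-B3LYP	S4	6.47	0.000	nOpi*2
thymine	CAM-B3LYP	S5	6.67	0.055	pipi*2
thymine	CAM-B3LYP	S6	6.73	0.218	pipi*3
thymine	PBE0	S1	4.89	0.000	nOpi*1
thymine	PBE0	S2	5.13	0.154	pipi*1
thymine	PBE0	S3	5.80	0.000	piRysigma1
thymine	PBE0	S4	6.10	0.000	nOpi*2
thymine	PBE0	S5	6.23	0.071	pipi*2
thymine	PBE0	S6	6.45	0.155	pipi*3
cytosine	CAM-B3LYP	S1	5.01	0.067	pipi*1
cytosine	CAM-B3LYP	S2	5.29	0.002	nNpi*1
cytosine	CAM-B3LYP	S4	5.91	0.000	nOpi*1
cytosine	CAM-B3LYP	S5	5.94	0.134	pipi*2
cytosine	CAM-B3LYP	S6	6.13	0.000	nOpi*2
cytosine	PBE0	S1	4.79	0.047	pipi*1
cytosine	PBE0	S2	4.97	0.001	nNpi*1+nOpi*1
cytosine	PBE0	S3	5.36	0.001	nNpi*1-nOpi*1
cytosine	PBE0	S4	5.61	0.099	pipi*2
cytosine	PBE0	S6	5.84	0.000	nOpi*2
adenine	CAM-B3LYP	S1	5.37	0.000	nNpi*1
adenine	CAM-B3LYP	S2	5.39	0.286	La
adenine	CAM-B3LYP	S3	5.52	0.015	Lb
adenine	CAM-B3LYP	S4	5.87	0.009	piRysigma1
adenine	PBE0	S1	5.11	0.001	nNpi*1
adenine	PBE0	S2	5.16	0.231	La
adenine	PBE0	S3	5.41	0.037	Lb
adenine	PBE0	S4	5.65	0.007	piRysigma1
guanine-9H	CAM-B3LYP	S1	5.18	0.173	La
guanine-9H	CAM-B3LYP	S2	5.22	0.003	piRysigma1
guanine-9H	CAM-B3LYP	S3	5.61	0.000	nOpi*1
guanine-9H	CAM-B3LYP	S4	5.63	0.336	Lb
guanine-9H	PBE0	S1	4.86	0.002	piRysigma1
guanine-9H	PBE0	S2	5.04	0.153	La
guanine-9H	PBE0	S3	5.36	0.282	Lb
guanine-9H	PBE0	S5	5.47	0.000	nOpi*1
guanine-7H	CAM-B3LYP	S1	4.91	0.151	La
guanine-7H	CAM-B3LYP	S2	5.30	0.004	piRysigma1
guanine-7H	CAM-B3LYP	S3	5.51	0.000	nOpi*1+nN9pi*
guanine-7H	CAM-B3LYP	S5	5.87	0.158	Lb
guanine-7H	PBE0	S1	4.72	0.127	La
guanine-7H	PBE0	S2	4.98	0.003	piRysigma1
guanine-7H	PBE0	S3	5.25	0.000	nOpi*1+nN9pi*
guanine-7H	PBE0	S5	5.59	0.122	Lb
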