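pre	post	all_0.75	all_1.5	all_2.5	all_3.75	pruned_2.5	bio
L23_PC	L23_PC	0.44	0.50	0.55	0.59	0.06	0.055
L4_SS	L23_PC	0.25	0.32	0.36	0.40	0.01	0.03
L4_SP	L4_SP	0.52	0.57	0.62	0.66	0.06	0.07
L5_MC	L5_TTPC1	0.89	0.95	0.98	0.99	0.10	0.33
L5_MC	L5_TTPC2	0.88	0.94	0.97	0.99	0.10	0.33
L5_STPC	L5_STPC	0.36	0.42	0.47	0.52	0.05	0.03
L5_TTPC1	L5_TTPC1	0.62	0.71	0.78	0.85	0.07	0.12
L5_TTPC2	L5_TTPC1	0.64	0.72	0.79	0.85	0.09	0.12
L5_TTPC1	L5_TTPC2	0.66	0.74	0.82	0.88	0.08	0.12
L5_TTPC2	L5_TTPC2	0.66	0.75	0.83	0.9	0.09	0.12
L6_TPC_L1	L6_TPC_L1	0.37	0.44	0.48	0.52	0.07	0.039
L6_TPC_L4	L6_TPC_L1	0.37	0.43	0.48	0.53	0.06	0.039
L6_TPC_L1	L6_TPC_L4	0.33	0.37	0.40	0.42	0.08	0.039
L6_TPC_L4	L6_TPC_L4	0.34	0.37	0.39	0.42	0.05	0.039
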