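pre	post	all_2.5	pruned_0.75	pruned_1.5	pruned_2.5	pruned_3.75	predictive_2.5	bio
L23_BTC	L23_PC	3.43	15.0	15.9	16.6	17.4	13.3	15.0
L23_LBC	L23_PC	4.12	15.0	16.3	16.7	17.3	16.0	14.5
L23_MC	L23_PC	3.05	11.2	11.7	12.1	12.7	11.5	11.2
L23_NBC	L23_PC	3.78	15.6	16.6	17.3	18.7	14.4	15.8
L23_SBC	L23_PC	4.95	20.2	21.6	22.8	24.8	18.3	20.5
L23_PC	L23_PC	2.01	2.8	2.8	2.9	2.8	3.1	2.9
L23_PC	L23_LBC	2.16	7.8	7.9	8.5	8.3	8.5	7.1
L23_PC	L23_NBC	2.09	3.8	3.8	3.9	3.7	8.0	3.4
L23_LBC	L23_LBC	4.20	13.7	15.0	14.8	15.6	17.6	12.3
L23_SBC	L23_LBC	5.25	14.4	15.2	14.9	15.6	20.3	12.3
L23_LBC	L23_SBC	4.02	13.2	14.4	15.0	15.7	16.0	12.3
L23_SBC	L23_SBC	4.79	13.8	14.9	15.4	15.7	18.9	12.3
L4_BTC	L4_PC	3.67	15.1	16.3	16.6	18.1	14.8	15.0
L4_LBC	L4_PC	4.12	15.1	16.0	16.2	16.9	15.0	14.5
L4_MC	L4_PC	3.64	11.4	11.9	12.3	12.4	14.4	11.2
L4_NBC	L4_PC	5.34	16.5	17.5	18.0	18.5	19.0	15.8
L4_SBC	L4_PC	5.65	21.4	22.7	23.9	24.4	19.7	20.5
L4_PC	L4_LBC	2.24	7.7	7.9	7.9	7.9	8.3	7.1
L4_PC	L4_NBC	2.24	3.9	3.8	3.8	3.7	8.3	3.4
L4_LBC	L4_LBC	4.31	13.9	14.0	14.1	14.6	15.2	12.3
L4_SBC	L4_LBC	6.06	14.1	14.5	14.8	14.6	20.8	12.3
L4_LBC	L4_SBC	4.14	13.4	13.6	14.7	14.3	16.3	12.3
L4_SBC	L4_SBC	5.84	13.7	14.0	13.6	14.4	20.2	12.3
L4_SP	L4_SP	2.05	3.4	3.6	3.5	3.5	3.1	3.4
L4_SS	L23_PC	1.70	4.3	4.6	4.8	4.7	2.5	4.5
L5_BTC	L5_TTPC1	4.59	17.3	17.6	18.4	18.9	18.3	15.0
L5_MC	L5_TTPC1	5.12	13.0	13.4	13.5	13.6	18.4	12.0
L5_BTC	L5_TTPC2	4.70	16.8	17.9	18.8	19.3	18.9	15.0
L5_MC	L5_TTPC2	5.29	13.2	13.7	13.7	13.8	19.4	12.0
L5_STPC	L5_STPC	2.40	4.0	4.2	4.2	4.3	3.9	4.0
L5_TTPC1	L5_MC	2.43	9.0	9.1	9.2	9.5	9.4	8.5
L5_TTPC1	L5_TTPC1	3.79	5.9	6.1	6.2	6.3	6.0	5.6
L5_TTPC1	L5_TTPC2	3.75	5.9	6.2	6.1	6.3	5.9	5.6
L5_TTPC2	L5_MC	2.50	9.2	9.2	9.2	9.7	9.7	8.5
L5_TTPC2	L5_TTPC1	3.94	5.8	6.0	6.0	6.2	6.3	5.6
L5_TTPC2	L5_TTPC2	3.89	5.9	6.0	6.0	6.1	6.2	5.6
L6_BTC	L6_TPC_L1	4.04	16.1	17.5	18.3	19.5	16.9	15.0
L6_BTC	L6_TPC_L4	3.83	15.9	17.1	18.2	19.3	16.0	15.0
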