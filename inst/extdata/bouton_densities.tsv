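m_type	all_2.5	pruned_0.75	pruned_1.5	pruned_2.5	pruned_3.75	predictive_2.5	bio
L1_DAC	3.32	0.13	0.13	0.13	0.13	0.15	0.18
L1_DLAC	3.53	0.18	0.19	0.20	0.20	0.23	0.20
L1_HAC	2.96	0.16	0.20	0.19	0.21	0.19	0.21
L1_NGC_DA	3.28	0.16	0.17	0.16	0.18	0.19	0.20
L1_NGC_SA	3.25	0.16	0.16	0.16	0.16	0.18	0.18
L1_SLAC	3.51	0.13	0.12	0.15	0.13	0.15	0.18
L23_BP	3.27	0.20	0.20	0.19	0.20	0.23	0.19
L23_BTC	2.82	0.14	0.19	0.20	0.20	0.18	0.20
L23_DBC	3.29	0.24	0.25	0.24	0.25	0.20	0.27
L23_LBC	3.20	0.10	0.13	0.14	0.15	0.17	0.17
L23_MC	3.01	0.14	0.23	0.23	0.24	0.19	0.24
L23_NBC	2.99	0.13	0.20	0.21	0.21	0.19	0.21
L23_SBC	3.26	0.14	0.21	0.21	0.21	0.20	0.23
L4_BP	3.34	0.12	0.11	0.11	0.11	0.18	0.13
L4_BTC	3.25	0.15	0.18	0.17	0.19	0.21	0.19
L4_DBC	3.46	0.26	0.27	0.27	0.26	0.22	0.26
L4_LBC	3.60	0.15	0.17	0.19	0.18	0.20	0.21
L4_MC	3.22	0.16	0.17	0.19	0.19	0.18	0.20
L4_NBC	3.53	0.18	0.20	0.19	0.20	0.24	0.19
L4_SBC	3.69	0.15	0.18	0.19	0.19	0.22	0.20
L4_SP	3.89	0.18	0.21	0.21	0.21	0.24	0.22
L4_SS	3.42	0.14	0.17	0.17	0.17	0.20	0.18
L5_BP	3.76	0.16	0.16	0.16	0.16	0.24	0.16
L5_BTC	3.93	0.13	0.12	0.13	0.13	0.19	0.16
L5_DBC	3.84	0.19	0.19	0.19	0.20	0.22	0.21
L5_LBC	4.05	0.15	0.15	0.15	0.15	0.22	0.17
L5_MC	3.89	0.19	0.19	0.17	0.19	0.24	0.19
L5_NBC	3.60	0.17	0.17	0.18	0.17	0.21	0.19
L5_SBC	4.08	0.21	0.21	0.21	0.22	0.25	0.22
L5_TTPC1	3.58	0.12	0.13	0.14	0.14	0.20	0.15
L5_TTPC2	3.56	0.13	0.14	0.14	0.15	0.22	0.15
L5_UTPC	3.36	0.16	0.20	0.20	0.20	0.20	0.21
L6_BPC	2.76	0.13	0.18	0.19	0.18	0.15	0.19
L6_DBC	2.74	0.06	0.06	0.07	0.06	0.13	0.08
L6_LBC	2.86	0.14	0.13	0.13	0.14	0.18	0.14
L6_MC	2.97	0.13	0.13	0.14	0.13	0.16	0.15
L6_NBC	2.51	0.11	0.11	0.12	0.12	0.12	0.16
L6_NGC	2.99	0.21	0.43	0.35	0.44	0.19	0.43
L6_SBC	2.88	0.17	0.18	0.18	0.17	0.16	0.19
L6_UTPC	2.40	0.15	0.19	0.20	0.20	0.15	0.20
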