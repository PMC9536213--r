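m_type	layer	vpl	vpm	pom
L23_PC	L23	15	15	20
L23_MC	L23	15	15	20
L23_BTC	L23	15	15	20
L23_DBC	L23	15	15	20
L23_BP	L23	15	15	20
L23_LBC	L23	15	15	20
L23_NBC	L23	15	15	20
L23_SBC	L23	15	15	20
L23_ChC	L23	15	15	20
L1_DAC	L1	5	5	25
L1_NGC	L1	5	5	25
L1_HAC	L1	5	5	25
L4_PC	L4	45	45	10
L4_SS	L4	45	45	10
L4_SP	L4	45	45	10
L4_MC	L4	45	45	10
L4_LBC	L4	45	45	10
L4_NBC	L4	45	45	10
L4_SBC	L4	45	45	10
L4_BTC	L4	45	45	10
L4_DBC	L4	45	45	10
L5_TTPC1	L5	30	30	25
L5_TTPC2	L5	30	30	25
L5_STPC	L5	30	30	25
L5_UTPC	L5	30	30	25
L5_MC	L5	30	30	25
L5_LBC	L5	30	30	25
L5_NBC	L5	30	30	25
L5_BTC	L5	30	30	25
L5_SBC	L5	30	30	25
L5_ChC	L5	30	30	25
L6_TPC_L1	L6	25	25	10
L6_TPC_L4	L6	25	25	10
L6_IPC	L6	25	25	10
L6_BPC	L6	25	25	10
L6_UTPC	L6	25	25	10
L6_MC	L6	25	25	10
L6_LBC	L6	25	25	10
L6_NBC	L6	25	25	10
L6_SBC	L6	25	25	10
L6_BTC	L6	25	25	10
L6_DBC	L6	25	25	10
L6_BP	L6	25	25	10
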