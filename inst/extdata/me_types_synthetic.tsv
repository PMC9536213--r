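me_type	layer	m_type	e_type	excitatory	count
L1_DAC_cNAC	L1	DAC	cNAC	FALSE	150
L1_NGC_cNAC	L1	NGC	cNAC	FALSE	110
L1_HAC_bNAC	L1	HAC	bNAC	FALSE	78
L23_PC_cADpyr	L23	PC	cADpyr	TRUE	6510
L23_MC_cAC	L23	MC	cAC	FALSE	200
L23_BTC_cAC	L23	BTC	cAC	FALSE	120
L23_DBC_bAC	L23	DBC	bAC	FALSE	100
L23_BP_cNAC	L23	BP	cNAC	FALSE	80
L23_LBC_cNAC	L23	LBC	cNAC	FALSE	180
L23_NBC_dNAC	L23	NBC	dNAC	FALSE	160
L23_SBC_bNAC	L23	SBC	bNAC	FALSE	110
L23_ChC_cAC	L23	ChC	cAC	FALSE	64
L4_PC_cADpyr	L4	PC	cADpyr	TRUE	2000
L4_SS_cADpyr	L4	SS	cADpyr	TRUE	1400
L4_SP_cADpyr	L4	SP	cADpyr	TRUE	563
L4_MC_cAC	L4	MC	cAC	FALSE	120
L4_LBC_cAC	L4	LBC	cAC	FALSE	150
L4_NBC_cNAC	L4	NBC	cNAC	FALSE	130
L4_SBC_dNAC	L4	SBC	dNAC	FALSE	100
L4_BTC_cAC	L4	BTC	cAC	FALSE	100
L4_DBC_cAC	L4	DBC	cAC	FALSE	93
L5_TTPC1_cADpyr	L5	TTPC1	cADpyr	TRUE	1600
L5_TTPC2_cADpyr	L5	TTPC2	cADpyr	TRUE	1800
L5_STPC_cADpyr	L5	STPC	cADpyr	TRUE	1000
L5_UTPC_cADpyr	L5	UTPC	cADpyr	TRUE	686
L5_MC_bAC	L5	MC	bAC	FALSE	300
L5_LBC_bAC	L5	LBC	bAC	FALSE	220
L5_NBC_bSTUT	L5	NBC	bSTUT	FALSE	180
L5_BTC_cNAC	L5	BTC	cNAC	FALSE	140
L5_SBC_cAC	L5	SBC	cAC	FALSE	100
L5_ChC_cNAC	L5	ChC	cNAC	FALSE	88
L6_TPC_L1_cADpyr	L6	TPC_L1	cADpyr	TRUE	3000
L6_TPC_L4_cADpyr	L6	TPC_L4	cADpyr	TRUE	3200
L6_IPC_cADpyr	L6	IPC	cADpyr	TRUE	2600
L6_BPC_cADpyr	L6	BPC	cADpyr	TRUE	1400
L6_UTPC_cADpyr	L6	UTPC	cADpyr	TRUE	808
L6_MC_cAC	L6	MC	cAC	FALSE	380
L6_LBC_bNAC	L6	LBC	bNAC	FALSE	330
L6_NBC_cSTUT	L6	NBC	cSTUT	FALSE	300
L6_SBC_cAC	L6	SBC	cAC	FALSE	240
L6_BTC_cAC	L6	BTC	cAC	FALSE	180
L6_DBC_cAC	L6	DBC	cAC	FALSE	156
L6_BP_bNAC	L6	BP	bNAC	FALSE	120
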