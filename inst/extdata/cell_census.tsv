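cell_type	N	P_SCS	P_BFOLLICLE	P_TCELL_AREA	P_MEDULLA	EV_CCR7	EV_CCL19	EV_CCL21	EV_ECM	EV_ACKR4
T_cell	1000000	0	0.02	0.9	0.01	0.5	0	0	0	0
B_cell	500000	0	0.85	0.1	0.01	0.2	0	0	0	0
DC	30000	0.02	0.02	0.6	0.2	0.5	0	0	0	0
macrophage	50000	0.05	0.02	0.2	0.5	0.05	0	0	0	0
LEC	20000	0.9	0	0	0.1	0	0	0	0.08	1
BEC	10000	0	0	0.6	0.3	0	0	0	0	0
FRC	160000	0	0	0.75	0.06	1	1	1	0.85	0
FDC	10000	0	0.9	0	0	0	0	0	0.004	0
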