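gene	k_sp	k_dp	k_sr	k_dr
NQO1	42	0.046	2.1	0.14
SOD1	88	0.017	3.4	0.10
POR	15	0.058	1.2	0.17
GSR	24	0.039	1.5	0.12
TXNRD1	31	0.052	1.8	0.15
G6PD	47	0.043	2.6	0.11
GLUD1	36	0.030	2.2	0.13
GPX1	65	0.022	2.9	0.10
CAT	73	0.014	3.1	0.09
PRX1	95	0.012	3.8	0.08
PRX2	81	0.015	3.3	0.09
TXN	58	0.025	2.7	0.12
GLRX	19	0.048	1.4	0.16
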