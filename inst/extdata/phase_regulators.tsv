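# phase	regulator	class
phase	regulator	class
G1	SWI4	tf
G1	MBP1	tf
G1	STB1	tf
G1	SWI6	tf
G1	ACE2	tf
G1	SKN7	tf
G1	CLN3	cdc
G1	FUS3	cdc
G1	FAR1	cdc
G1	CDC36	cdc
G1	CDC39	cdc
G1	CLN2	cdc
G1	CDC37	cdc
G1	CDC28	cdc
G1	CLN1	cdc
S	SWI4	tf
S	MBP1	tf
S	NDD1	tf
S	SWI6	tf
S	SKN7	tf
S	CDC24	cdc
S	CDC7	cdc
S	CDC8	cdc
S	CDC21	cdc
G2	FKH1	tf
G2	FKH2	tf
G2	NDD1	tf
G2	MCM1	tf
G2	CDC11	cdc
G2	CLB2	cdc
G2	CDC15	cdc
G2	CLB4	cdc
G2	CDC28	cdc
G2	CDC3	cdc
G2	CDC5	cdc
G2	CDC14	cdc
G2	CLB1	cdc
G2	CLB3	cdc
M	MCM1	tf
M	SWI5	tf
M	ACE2	tf
M	CDC28	cdc
M	CLB1	cdc
M	CLB2	cdc
M	CLB3	cdc
M	CLB4	cdc
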