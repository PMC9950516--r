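record	id	type	x	y	z	source	detector	channel
optode	S1	source	0	0	0	NA	NA	NA
optode	S2	source	60	0	0	NA	NA	NA
optode	S3	source	30	30	0	NA	NA	NA
optode	S4	source	90	30	0	NA	NA	NA
optode	S5	source	0	60	0	NA	NA	NA
optode	S6	source	60	60	0	NA	NA	NA
optode	S7	source	30	90	0	NA	NA	NA
optode	S8	source	90	90	0	NA	NA	NA
optode	S9	source	30	0	30	NA	NA	NA
optode	S10	source	90	0	30	NA	NA	NA
optode	S11	source	0	30	30	NA	NA	NA
optode	S12	source	60	30	30	NA	NA	NA
optode	S13	source	30	60	30	NA	NA	NA
optode	S14	source	90	60	30	NA	NA	NA
optode	S15	source	0	90	30	NA	NA	NA
optode	S16	source	60	90	30	NA	NA	NA
optode	D1	detector	30	0	0	NA	NA	NA
optode	D2	detector	90	0	0	NA	NA	NA
optode	D3	detector	0	30	0	NA	NA	NA
optode	D4	detector	60	30	0	NA	NA	NA
optode	D5	detector	30	60	0	NA	NA	NA
optode	D6	detector	90	60	0	NA	NA	NA
optode	D7	detector	0	90	0	NA	NA	NA
optode	D8	detector	60	90	0	NA	NA	NA
optode	D9	detector	0	0	30	NA	NA	NA
optode	D10	detector	60	0	30	NA	NA	NA
optode	D11	detector	30	30	30	NA	NA	NA
optode	D12	detector	90	30	30	NA	NA	NA
optode	D13	detector	0	60	30	NA	NA	NA
optode	D14	detector	60	60	30	NA	NA	NA
optode	D15	detector	30	90	30	NA	NA	NA
optode	D16	detector	90	90	30	NA	NA	NA
optode	Nz	reference	45	-60	0	NA	NA	NA
optode	Cz	reference	45	150	0	NA	NA	NA
optode	AL	reference	-40	45	0	NA	NA	NA
optode	RL	reference	130	45	0	NA	NA	NA
channel	CH1	channel	NA	NA	NA	S1	D1	1
channel	CH2	channel	NA	NA	NA	S2	D1	2
channel	CH3	channel	NA	NA	NA	S2	D2	3
channel	CH4	channel	NA	NA	NA	S1	D3	4
channel	CH5	channel	NA	NA	NA	S3	D1	5
channel	CH6	channel	NA	NA	NA	S2	D4	6
channel	CH7	channel	NA	NA	NA	S4	D2	7
channel	CH8	channel	NA	NA	NA	S3	D3	8
channel	CH9	channel	NA	NA	NA	S3	D4	9
channel	CH10	channel	NA	NA	NA	S4	D4	10
channel	CH11	channel	NA	NA	NA	S5	D3	11
channel	CH12	channel	NA	NA	NA	S3	D5	12
channel	CH13	channel	NA	NA	NA	S6	D4	13
channel	CH14	channel	NA	NA	NA	S4	D6	14
channel	CH15	channel	NA	NA	NA	S5	D5	15
channel	CH16	channel	NA	NA	NA	S6	D5	16
channel	CH17	channel	NA	NA	NA	S6	D6	17
channel	CH18	channel	NA	NA	NA	S5	D7	18
channel	CH19	channel	NA	NA	NA	S7	D5	19
channel	CH20	channel	NA	NA	NA	S6	D8	20
channel	CH21	channel	NA	NA	NA	S8	D6	21
channel	CH22	channel	NA	NA	NA	S7	D7	22
channel	CH23	channel	NA	NA	NA	S7	D8	23
channel	CH24	channel	NA	NA	NA	S8	D8	24
channel	CH25	channel	NA	NA	NA	S1	D9	25
channel	CH26	channel	NA	NA	NA	S9	D1	26
channel	CH27	channel	NA	NA	NA	S2	D10	27
channel	CH28	channel	NA	NA	NA	S10	D2	28
channel	CH29	channel	NA	NA	NA	S11	D3	29
channel	CH30	channel	NA	NA	NA	S3	D11	30
channel	CH31	channel	NA	NA	NA	S12	D4	31
channel	CH32	channel	NA	NA	NA	S4	D12	32
channel	CH33	channel	NA	NA	NA	S5	D13	33
channel	CH34	channel	NA	NA	NA	S13	D5	34
channel	CH35	channel	NA	NA	NA	S6	D14	35
channel	CH36	channel	NA	NA	NA	S14	D6	36
channel	CH37	channel	NA	NA	NA	S15	D7	37
channel	CH38	channel	NA	NA	NA	S7	D15	38
channel	CH39	channel	NA	NA	NA	S16	D8	39
channel	CH40	channel	NA	NA	NA	S8	D16	40
channel	CH41	channel	NA	NA	NA	S9	D9	41
channel	CH42	channel	NA	NA	NA	S9	D10	42
channel	CH43	channel	NA	NA	NA	S10	D10	43
channel	CH44	channel	NA	NA	NA	S11	D9	44
channel	CH45	channel	NA	NA	NA	S9	D11	45
channel	CH46	channel	NA	NA	NA	S12	D10	46
channel	CH47	channel	NA	NA	NA	S10	D12	47
channel	CH48	channel	NA	NA	NA	S11	D11	48
channel	CH49	channel	NA	NA	NA	S12	D11	49
channel	CH50	channel	NA	NA	NA	S12	D12	50
channel	CH51	channel	NA	NA	NA	S11	D13	51
channel	CH52	channel	NA	NA	NA	S13	D11	52
channel	CH53	channel	NA	NA	NA	S12	D14	53
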