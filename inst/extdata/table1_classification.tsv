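# Published skate/lamprey classification table, transcribed verbatim.
# Each column of the printed table is one (target, region) pair; rows are the
# five subfamily-restricted HMM profiles. Cells are E-values with bit scores
# in parentheses in the original; two suspected typographic anomalies are
# preserved as printed ("79,9" with a decimal comma; "6.73E-3 (119.1)").
genome	target	region	subfamily	evalue	bit_score
little_skate	AESE012567234.1	TM1 to TM4	Type I	4.7E-28	107.9
little_skate	AESE012567234.1	TM1 to TM4	Type IIa-1	7.1E-50	178.5
little_skate	AESE012567234.1	TM1 to TM4	Type IIa-2	1.7E-47	107.7
little_skate	AESE012567234.1	TM1 to TM4	Type IIa-3	5.0E-41	149.8
little_skate	AESE012567234.1	TM1 to TM4	Type IIb	8.1E-41	149.0
little_skate	AESE011658775.1	TM1 to TM4	Type I	1.1E-34	129.2
little_skate	AESE011658775.1	TM1 to TM4	Type IIa-1	2.4E-60	212.4
little_skate	AESE011658775.1	TM1 to TM4	Type IIa-2	8.5E-68	236.5
little_skate	AESE011658775.1	TM1 to TM4	Type IIa-3	7.2E-64	223.8
little_skate	AESE011658775.1	TM1 to TM4	Type IIb	2.1E-50	180.0
little_skate	AESE011105720.1	TM1 to TM4	Type I	3.4E-48	173.2
little_skate	AESE011105720.1	TM1 to TM4	Type IIa-1	3.9E-43	127.5
little_skate	AESE011105720.1	TM1 to TM4	Type IIa-2	1.5E-31	199.1
little_skate	AESE011105720.1	TM1 to TM4	Type IIa-3	2.2E-32	121.8
little_skate	AESE011105720.1	TM1 to TM4	Type IIb	2.9E-35	131.0
little_skate	AESE010056425.1	TM6 to TM7	Type I	1.3E-19	79,9
little_skate	AESE010056425.1	TM6 to TM7	Type IIa-1	5.5E-33	122.6
little_skate	AESE010056425.1	TM6 to TM7	Type IIa-2	1.0E-25	99.5
little_skate	AESE010056425.1	TM6 to TM7	Type IIa-3	3.6E-25	97.7
little_skate	AESE010056425.1	TM6 to TM7	Type IIb	1.6E-23	92.2
little_skate	AESE011520245.1	TM6 to TM7	Type I	9.3E-29	109.2
little_skate	AESE011520245.1	TM6 to TM7	Type IIa-1	3.5E-33	123.2
little_skate	AESE011520245.1	TM6 to TM7	Type IIa-2	1.3E-40	147.3
little_skate	AESE011520245.1	TM6 to TM7	Type IIa-3	5.1E-39	142.1
little_skate	AESE011520245.1	TM6 to TM7	Type IIb	2.5E-21	117.2
little_skate	AESE012567234.1	TM6 to TM7	Type I	1.8E-38	140.4
little_skate	AESE012567234.1	TM6 to TM7	Type IIa-1	6.73E-3	119.1
little_skate	AESE012567234.1	TM6 to TM7	Type IIa-2	1.4E-30	115.1
little_skate	AESE012567234.1	TM6 to TM7	Type IIa-3	9.3E-28	106.0
little_skate	AESE012567234.1	TM6 to TM7	Type IIb	2.1E-32	120.6
lamprey	22569.4_6	Tm1 to Tm4	Type I	1.2E-44	138
lamprey	22569.4_6	Tm1 to Tm4	Type IIa-1	3.4E-75	237
lamprey	22569.4_6	Tm1 to Tm4	Type IIa-2	7.3E-61	191
lamprey	22569.4_6	Tm1 to Tm4	Type IIa-3	2.9E-59	185
lamprey	22569.4_6	Tm1 to Tm4	Type IIb	2.5E-54	169
lamprey	42790.2_1	Tm1 to Tm4	Type I	1.0E-33	103
lamprey	42790.2_1	Tm1 to Tm4	Type IIa-1	2.5E-59	186
lamprey	42790.2_1	Tm1 to Tm4	Type IIa-2	1.2E-49	154
lamprey	42790.2_1	Tm1 to Tm4	Type IIa-3	6.9E-47	145
lamprey	42790.2_1	Tm1 to Tm4	Type IIb	9.7E-46	141
lamprey	31731.1_3	Tm1 to Tm4	Type I	1.9E-23	69
lamprey	31731.1_3	Tm1 to Tm4	Type IIa-1	1.7E-41	128
lamprey	31731.1_3	Tm1 to Tm4	Type IIa-2	7.3E-34	103
lamprey	31731.1_3	Tm1 to Tm4	Type IIa-3	3.0E-32	97
lamprey	31731.1_3	Tm1 to Tm4	Type IIb	2.5E-31	95
lamprey	30359.1_1	Tm6 to Tm7	Type I	3.7E-36	110
lamprey	30359.1_1	Tm6 to Tm7	Type IIa-1	6.7E-48	138
lamprey	30359.1_1	Tm6 to Tm7	Type IIa-2	4.5E-39	119
lamprey	30359.1_1	Tm6 to Tm7	Type IIa-3	4.9E-38	116
lamprey	30359.1_1	Tm6 to Tm7	Type IIb	9.5E-37	111
lamprey	36401.1_5	Tm6 to Tm7	Type I	7.2E-30	90
lamprey	36401.1_5	Tm6 to Tm7	Type IIa-1	3.6E-45	138
lamprey	36401.1_5	Tm6 to Tm7	Type IIa-2	1.2E-32	98
lamprey	36401.1_5	Tm6 to Tm7	Type IIa-3	1.3E-32	98
lamprey	36401.1_5	Tm6 to Tm7	Type IIb	3.0E-33	100
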