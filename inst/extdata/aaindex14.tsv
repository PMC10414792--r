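residue	HOPT810101	EISD840101	MIYS990104	LIFS790101	MAXF760101	CEDJ970104	GRAR740102	KYTJ820101	MITS020101	DAWD720101	BIOV880101	CHAM810101	EISD860101	BIGC670101
A	-0.5	0.25	-0.04	0.92	1.43	7.9	8.1	1.8	0.0	2.5	16.0	0.52	0.67	52.6
C	-1.0	0.04	-0.38	1.16	0.94	1.9	5.5	2.5	0.0	3.0	168.0	0.62	0.38	68.3
D	3.0	-0.72	0.19	0.48	0.92	5.5	13.0	-3.5	0.0	2.5	-78.0	0.76	-1.2	68.4
E	3.0	-0.62	0.23	0.61	1.67	7.1	12.3	-3.5	1.27	5.0	-106.0	0.68	-0.76	84.7
F	-2.5	0.61	-0.38	1.25	1.19	3.9	5.2	2.8	0.0	6.5	189.0	0.7	2.3	113.9
G	0.0	0.16	0.09	0.61	0.46	7.1	9.0	-0.4	0.0	0.5	-13.0	0.0	0.0	36.3
H	-0.5	-0.4	-0.04	0.93	0.98	2.1	10.4	-3.2	1.45	6.0	50.0	0.7	0.64	91.9
I	-1.8	0.73	-0.34	1.81	1.04	5.2	5.2	4.5	0.0	5.5	151.0	1.02	1.9	102.0
K	3.0	-1.1	0.33	0.7	1.27	6.7	11.3	-3.9	3.67	7.0	-141.0	0.68	-0.57	105.1
L	-1.8	0.53	-0.37	1.3	1.36	8.6	4.9	3.8	0.0	5.5	145.0	0.98	1.9	102.0
M	-1.3	0.26	-0.3	1.19	1.53	2.4	5.7	1.9	0.0	6.0	124.0	0.78	2.4	97.7
N	0.2	-0.64	0.13	0.6	0.64	4.0	11.6	-3.5	0.0	5.0	-74.0	0.76	-0.6	75.7
P	0.0	-0.07	0.19	0.4	0.49	5.3	8.0	-1.6	0.0	5.5	-20.0	0.36	1.2	73.6
Q	0.2	-0.69	0.14	0.95	1.22	4.4	10.5	-3.5	1.25	6.0	-73.0	0.68	-0.22	89.7
R	3.0	-1.76	0.07	0.93	1.18	4.9	10.5	-4.5	2.45	7.5	-70.0	0.68	-2.1	109.1
S	0.3	-0.26	0.12	0.82	0.7	6.6	9.2	-0.8	0.0	3.0	-70.0	0.53	0.01	54.9
T	-0.4	-0.18	0.03	1.12	0.78	5.3	8.6	-0.7	0.0	5.0	-38.0	0.5	0.52	71.2
V	-1.5	0.54	-0.29	1.81	0.98	6.8	5.9	4.2	0.0	5.0	123.0	0.76	1.5	85.1
W	-3.4	0.37	-0.33	1.54	1.01	1.2	5.4	-0.9	6.93	7.0	145.0	0.7	2.6	135.4
Y	-2.3	0.02	-0.29	1.53	0.69	3.1	6.2	-1.3	5.06	7.0	53.0	0.7	1.6	116.2
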