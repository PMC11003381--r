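diet	ibw	sr	fr	fbw	sgr	fe	per	pre
Control	15.21	96.20	3.03	59.05	2.42	65.42	1.91	33.67
A33	15.15	96.67	2.94	61.38	2.50	69.74	2.06	35.54
A67	15.20	97.60	3.00	56.91	2.36	65.90	1.92	33.90
A100	15.18	96.20	3.06	53.68	2.25	61.79	1.81	31.52
B33	15.20	95.23	2.98	60.53	2.47	67.15	1.95	34.76
B67	15.23	96.67	2.95	60.21	2.45	68.30	1.99	35.52
B100	15.15	96.67	2.94	61.81	2.51	69.75	2.06	36.33
C33	15.07	95.70	2.95	60.25	2.48	68.23	2.00	34.14
C67	15.20	95.70	2.94	58.98	2.42	67.61	1.99	34.44
C100	15.26	96.67	2.97	59.05	2.42	66.82	1.98	35.25
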