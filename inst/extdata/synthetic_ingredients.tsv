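name	crude_protein	crude_lipid	lysine	methionine	threonine	arginine	leucine	isoleucine	valine	phenylalanine	histidine	asparagine	serine	glutamic_acid	glycine	alanine	tyrosine	proline	cysteine
fish_meal	65.0	8.0	4.90	1.80	2.70	3.80	4.70	2.80	3.20	2.60	1.90	5.90	2.50	8.20	4.20	4.00	2.00	2.80	0.60
t_molitor_meal	52.0	12.0	2.90	0.80	2.10	2.60	3.70	2.30	3.00	1.80	1.60	4.20	2.50	6.00	2.70	3.80	3.50	3.30	0.50
chlorella_meal	55.0	8.0	3.00	1.20	2.40	3.30	4.60	2.10	3.10	2.60	1.10	4.70	2.20	6.30	3.00	4.30	1.90	2.50	0.60
cap	82.0	2.0	5.90	2.00	3.60	4.00	6.30	3.90	4.70	3.50	1.60	7.40	3.10	10.50	3.90	5.40	3.00	3.00	0.80
cpc	62.0	1.0	2.60	0.90	1.90	6.90	3.50	1.90	2.70	3.40	1.80	5.60	2.70	12.20	2.60	2.40	1.80	2.30	1.00
rapeseed_meal	38.0	2.0	2.00	0.70	1.60	2.20	2.60	1.50	1.90	1.50	1.00	2.70	1.60	6.50	1.90	1.60	1.10	2.20	0.90
soybean_meal	46.0	1.5	2.80	0.60	1.80	3.30	3.50	2.10	2.20	2.30	1.20	5.20	2.30	8.20	1.90	2.00	1.60	2.30	0.70
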