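symbol	covalent_radius	vdw_radius	mass
H	0.31	1.10	1.008
He	0.28	1.40	4.0026
Li	1.28	1.81	6.94
Be	0.96	1.53	9.0122
B	0.84	1.92	10.81
C	0.76	1.70	12.011
N	0.71	1.55	14.007
O	0.66	1.52	15.999
F	0.57	1.47	18.998
Ne	0.58	1.54	20.180
Na	1.66	2.27	22.990
Mg	1.41	1.73	24.305
Al	1.21	1.84	26.982
Si	1.11	2.10	28.085
P	1.07	1.80	30.974
S	1.05	1.80	32.06
Cl	1.02	1.75	35.45
Ar	1.06	1.88	39.948
K	2.03	2.75	39.098
Ca	1.76	2.31	40.078
Sc	1.70	2.15	44.956
Ti	1.60	2.11	47.867
V	1.53	2.07	50.942
Cr	1.39	2.06	51.996
Mn	1.39	2.05	54.938
Fe	1.32	2.04	55.845
Co	1.26	2.00	58.933
Ni	1.24	1.97	58.693
Cu	1.32	1.96	63.546
Zn	1.22	2.01	65.38
Ga	1.22	1.87	69.723
Ge	1.20	2.11	72.630
As	1.19	1.85	74.922
Se	1.20	1.90	78.971
Br	1.20	1.85	79.904
Kr	1.16	2.02	83.798
Rb	2.20	3.03	85.468
Sr	1.95	2.49	87.62
Y	1.90	2.32	88.906
Zr	1.75	2.23	91.224
Nb	1.64	2.18	92.906
Mo	1.54	2.17	95.95
Tc	1.47	2.16	98
Ru	1.46	2.13	101.07
Rh	1.42	2.10	102.91
Pd	1.39	2.10	106.42
Ag	1.45	2.11	107.87
Cd	1.44	2.18	112.41
In	1.42	1.93	114.82
Sn	1.39	2.17	118.71
Sb	1.39	2.06	121.76
Te	1.38	2.06	127.60
I	1.39	1.98	126.90
Xe	1.40	2.16	131.29
Cs	2.44	3.43	132.91
Ba	2.15	2.68	137.33
La	2.07	2.43	138.91
Ce	2.04	2.42	140.12
Hf	1.75	2.23	178.49
Ta	1.70	2.22	180.95
W	1.62	2.18	183.84
Re	1.51	2.16	186.21
Os	1.44	2.16	190.23
Ir	1.41	2.13	192.22
Pt	1.36	2.13	195.08
Au	1.36	2.14	196.97
Hg	1.32	2.23	200.59
Tl	1.45	1.96	204.38
Pb	1.46	2.02	207.2
Bi	1.48	2.07	208.98
Po	1.40	1.97	209
At	1.50	2.02	210
Rn	1.50	2.20	222
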