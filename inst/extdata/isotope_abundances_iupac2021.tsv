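element	mass_number	exact_mass	abundance
H	1	1.00782503207	0.999885
H	2	2.01410177785	0.000115
C	12	12.0000000	0.9893
C	13	13.00335483507	0.0107
N	14	14.00307400443	0.99636
N	15	15.00010889888	0.00364
O	16	15.99491461957	0.99757
O	17	16.99913175650	0.00038
O	18	17.99915961286	0.00205
F	19	18.99840316273	1.0
Na	23	22.98976928196	1.0
Mg	24	23.985041697	0.7899
Mg	25	24.985836976	0.1000
Mg	26	25.982592968	0.1101
Si	28	27.97692653465	0.92223
Si	29	28.97649466490	0.04685
Si	30	29.973770136	0.03092
P	31	30.97376199842	1.0
S	32	31.9720711744	0.9499
S	33	32.9714589098	0.0075
S	34	33.967867004	0.0425
S	36	35.96708071	0.0001
Cl	35	34.968852682	0.7576
Cl	37	36.965902602	0.2424
K	39	38.9637064864	0.932581
K	40	39.963998166	0.000117
K	41	40.9618252579	0.067302
Ca	40	39.962590863	0.96941
Ca	42	41.95861783	0.00647
Ca	43	42.95876644	0.00135
Ca	44	43.95548156	0.02086
Ca	46	45.95368990	0.00004
Ca	48	47.95252276	0.00187
Fe	54	53.93960899	0.05845
Fe	56	55.93493633	0.91754
Fe	57	56.93539284	0.02119
Fe	58	57.93327443	0.00282
Cu	63	62.92959772	0.6915
Cu	65	64.92778970	0.3085
Zn	64	63.92914201	0.4917
Zn	66	65.92603381	0.2773
Zn	67	66.92712775	0.0404
Zn	68	67.92484455	0.1845
Zn	70	69.9253192	0.0061
Br	79	78.9183376	0.5069
Br	81	80.9162897	0.4931
I	127	126.9044719	1.0
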