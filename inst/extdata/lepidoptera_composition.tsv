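species	partition	size_bp	pct_A	pct_G	pct_T	pct_C	at_pct	at_skew	gc_skew
C_menciana	whole	15369	41.28	7.61	38.78	12.32	80.06	0.031	-0.236
A_ipsilon	whole	15377	40.38	7.71	40.87	11.04	81.25	-0.006	-0.178
L_dispar	whole	15569	40.58	7.57	39.30	12.55	79.88	0.016	-0.248
H_cunea	whole	15481	40.58	7.55	39.81	12.06	80.39	0.010	-0.230
A_formosae	whole	15453	38.67	7.53	40.83	12.98	79.49	-0.027	-0.266
O_lunifer	whole	15593	40.09	7.56	37.75	14.60	77.84	0.030	-0.318
P_flavescens	whole	15659	40.07	7.87	40.80	11.26	80.87	-0.009	-0.177
B_mandarina	whole	15682	43.11	7.40	38.48	11.01	81.59	0.057	-0.196
A_selene	whole	15236	38.54	8.05	40.37	13.03	78.91	-0.023	-0.236
A_pernyi	whole	15566	39.22	7.77	40.94	12.07	80.16	-0.021	-0.216
E_pyretorum	whole	15327	39.17	7.63	41.65	11.55	80.82	-0.031	-0.204
T_hypsalis	whole	15329	40.00	7.67	41.42	10.92	81.41	-0.017	-0.175
L_haraldusalis	whole	15213	40.47	7.66	41.04	10.83	81.52	-0.007	-0.172
C_pomonella	whole	15253	39.92	7.88	40.21	11.99	80.13	-0.004	-0.207
G_dimorpha	whole	15831	39.99	7.77	40.85	11.39	80.84	-0.011	-0.189
L_taibai	whole	15553	40.37	7.39	41.10	11.14	81.46	-0.009	-0.202
A_ilia	whole	15242	39.77	7.75	40.68	11.80	80.45	-0.011	-0.207
C_menciana	PCG	11190	40.68	8.40	37.72	13.20	78.42	0.038	-0.222
C_menciana	tRNA	1472	42.12	7.81	40.01	10.05	82.13	0.026	-0.125
C_menciana	rRNA	2137	42.82	4.73	40.99	11.46	83.81	0.022	-0.416
C_menciana	control	372	44.35	2.42	50.00	3.23	94.35	-0.060	-0.143
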