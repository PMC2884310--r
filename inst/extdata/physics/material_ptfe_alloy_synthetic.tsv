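# material: ptfe_alloy
# density_g_cm3: 21.644
# effective_Z: 73
# mu: linear attenuation coefficient (1/cm); muC_over_mu: Compton fraction;
# b,c,a,xK,d: GP buildup coefficients (synthetic in-package fit, point isotropic)
E_MeV	mu_per_cm	muC_over_mu	b	c	a	xK	d
0.05	129.682	0.02	1.02	1.03	-0.02	14	-0.02
0.06	82.2688	0.03	1.04	1.04	-0.02	14	-0.02
0.08	130.709	0.02	1.07	1.05	-0.02	14	-0.02
0.1	88.0638	0.04	1.09	1.07	-0.02	14	-0.02
0.15	31.0998	0.09	1.16	1.09	-0.02	14	-0.02
0.2	15.5577	0.17	1.22	1.11	-0.02	14	-0.02
0.3	6.588	0.33	1.29	1.13	-0.02	14	-0.02
0.4	3.9825	0.46	1.34	1.14	-0.02	14	-0.02
0.5	2.88359	0.55	1.37	1.14	-0.02	14	-0.02
0.6	2.31608	0.61	1.39	1.14	-0.02	14	-0.02
0.8	1.73754	0.69	1.42	1.15	-0.02	14	-0.02
1	1.44214	0.74	1.43	1.15	-0.02	14	-0.02
1.25	1.22721	0.77	1.44	1.15	-0.02	14	-0.02
1.5	1.10311	0.78	1.44	1.15	-0.02	14	-0.02
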