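# material: tungsten
# density_g_cm3: 19.3
# effective_Z: 74
# mu: linear attenuation coefficient (1/cm); muC_over_mu: Compton fraction;
# b,c,a,xK,d: GP buildup coefficients (synthetic in-package fit, point isotropic)
E_MeV	mu_per_cm	muC_over_mu	b	c	a	xK	d
0.05	114.816	0.02	1.03	1.04	-0.02	14	-0.02
0.06	71.6609	0.03	1.05	1.05	-0.02	14	-0.02
0.08	150.733	0.02	1.08	1.06	-0.02	14	-0.02
0.1	85.6534	0.04	1.1	1.08	-0.02	14	-0.02
0.15	30.5133	0.1	1.18	1.1	-0.02	14	-0.02
0.2	15.1389	0.18	1.25	1.12	-0.02	14	-0.02
0.3	6.24934	0.35	1.32	1.14	-0.02	14	-0.02
0.4	3.71525	0.48	1.38	1.15	-0.02	14	-0.02
0.5	2.65954	0.57	1.4	1.15	-0.02	14	-0.02
0.6	2.10949	0.63	1.42	1.15	-0.02	14	-0.02
0.8	1.55674	0.71	1.44	1.16	-0.02	14	-0.02
1	1.27727	0.76	1.45	1.16	-0.02	14	-0.02
1.25	1.07636	0.79	1.46	1.16	-0.02	14	-0.02
1.5	0.965	0.8	1.46	1.16	-0.02	14	-0.02
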