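# material: steel
# density_g_cm3: 8.02
# effective_Z: 26
# mu: linear attenuation coefficient (1/cm); muC_over_mu: Compton fraction;
# b,c,a,xK,d: GP buildup coefficients (synthetic in-package fit, point isotropic)
E_MeV	mu_per_cm	muC_over_mu	b	c	a	xK	d
0.05	15.7032	0.08	1.25	1.1	-0.05	12	-0.03
0.06	9.6641	0.12	1.35	1.14	-0.05	12	-0.03
0.08	4.7735	0.25	1.45	1.18	-0.05	12	-0.03
0.1	2.98103	0.38	1.55	1.22	-0.05	12	-0.03
0.15	1.57513	0.6	1.7	1.27	-0.05	12	-0.03
0.2	1.17092	0.72	1.78	1.3	-0.05	12	-0.03
0.3	0.881398	0.83	1.85	1.32	-0.05	12	-0.03
0.4	0.75388	0.88	1.88	1.32	-0.05	12	-0.03
0.5	0.674803	0.91	1.88	1.31	-0.05	12	-0.03
0.6	0.617861	0.92	1.87	1.3	-0.05	12	-0.03
0.8	0.53726	0.935	1.85	1.28	-0.05	12	-0.03
1	0.480799	0.94	1.82	1.26	-0.05	12	-0.03
1.25	0.42907	0.94	1.78	1.24	-0.05	12	-0.03
1.5	0.391617	0.935	1.75	1.22	-0.05	12	-0.03
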