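# material: air
# density_g_cm3: 0.001205
# effective_Z: 7.64
# mu: linear attenuation coefficient (1/cm); muC_over_mu: Compton fraction;
# b,c,a,xK,d: GP buildup coefficients (synthetic in-package fit, point isotropic)
E_MeV	mu_per_cm	muC_over_mu	b	c	a	xK	d
0.05	0.00025064	0.83	2.2	1.4	-0.07	10	-0.04
0.06	0.000225937	0.88	2.4	1.45	-0.07	10	-0.04
0.08	0.000200271	0.93	2.7	1.52	-0.07	10	-0.04
0.1	0.00018569	0.95	2.9	1.58	-0.07	10	-0.04
0.15	0.000163398	0.97	3	1.62	-0.07	10	-0.04
0.2	0.000148576	0.98	2.95	1.62	-0.07	10	-0.04
0.3	0.000128574	0.99	2.75	1.6	-0.07	10	-0.04
0.4	0.000114957	0.992	2.55	1.58	-0.07	10	-0.04
0.5	0.000104594	0.994	2.4	1.56	-0.07	10	-0.04
0.6	9.6882e-05	0.995	2.3	1.55	-0.07	10	-0.04
0.8	8.5073e-05	0.996	2.15	1.52	-0.07	10	-0.04
1	7.6638e-05	0.996	2.05	1.5	-0.07	10	-0.04
1.25	6.8444e-05	0.995	1.95	1.47	-0.07	10	-0.04
1.5	6.22985e-05	0.993	1.88	1.45	-0.07	10	-0.04
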