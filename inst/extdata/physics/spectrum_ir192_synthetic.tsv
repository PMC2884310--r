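# nuclide: Ir-192
# total_yield_per_decay: 2.364
# line yields rescaled at load time to the stated total (synthetic composite of published decay data)
E_MeV	yield
0.13634	0.00199
0.2008	0.00471
0.20579	0.03307
0.28327	0.00266
0.29596	0.2871
0.30846	0.297
0.31651	0.8286
0.37425	0.00726
0.41647	0.0067
0.46807	0.4781
0.48458	0.03184
0.48906	0.00438
0.58858	0.04517
0.60441	0.082
0.61246	0.0534
0.78457	0.00202
0.88454	0.02921
1.06148	0.053
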