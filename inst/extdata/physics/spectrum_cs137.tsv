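# nuclide: Cs-137
# total_yield_per_decay: 0.851
E_MeV	yield
0.662	0.851
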