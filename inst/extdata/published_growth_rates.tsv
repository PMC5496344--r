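co2_pct	nitrogen_source	mu_experimental	mu_predicted	error_pct
0.03	nitrate	0.0207	0.0169	22.1
0.03	ammonium	0.0206	0.0156	32.2
0.03	urea	0.0109	0.0098	11.1
0.03	nitrate	0.0203	0.0186	9.3
2	nitrate	0.0183	0.0207	11.8
5	nitrate	0.0185	0.0178	4.2
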