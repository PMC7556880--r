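>GBM_synthetic_GACCACCC
0.10	0.10	0.70	0.10
0.70	0.10	0.10	0.10
0.10	0.70	0.10	0.10
0.10	0.70	0.10	0.10
0.97	0.01	0.01	0.01
0.10	0.70	0.10	0.10
0.10	0.70	0.10	0.10
0.10	0.70	0.10	0.10
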