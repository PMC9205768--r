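cluster	ccf_a	ccf_b
1	0.02	0.96
2	0.97	0.01
3	0.99	0.98
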