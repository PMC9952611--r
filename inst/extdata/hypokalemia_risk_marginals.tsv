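variable	level	cases	controls
sex	female	60	3377
sex	male	45	4900
age	le18	9	632
age	19-64	47	4272
age	ge65	49	3373
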