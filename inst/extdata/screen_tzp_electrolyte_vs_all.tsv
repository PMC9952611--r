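event	a	b	c	d
hypokalemia	113	36094	77255	64492942
hyperkalemia	48	36159	227018	64343179
hyponatremia	33	36174	342483	64227714
hypernatremia	35	36172	44850	64525347
hypocalcemia	22	36185	155848	64414349
hypercalcemia	7	36200	99053	64471144
hypomagnesemia	28	36179	104301	64465896
hypermagnesemia	1	36206	11599	64558598
hypophosphatemia	7	36200	54216	64515981
hyperphosphatemia	10	36197	17537	64552660
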