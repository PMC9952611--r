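drug	a	b	c	d
amoxicillin/clavulanic acid	120	73848	311	130124
piperacillin/tazobactam	113	36094	318	167878
ampicillin/sulbactam	12	5034	419	198938
amoxicillin	81	59895	350	144077
ampicillin	26	6381	405	197591
piperacillin	6	1767	425	202205
flucloxacillin	20	3913	411	200059
cloxacillin	13	1742	418	202230
oxacillin	7	1727	424	202245
nafcillin	24	1299	407	202673
penicillin v	5	5860	426	198112
penicillin g	4	6412	427	197560
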