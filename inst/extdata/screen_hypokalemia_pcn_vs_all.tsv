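drug	a	b	c	d
amoxicillin/clavulanic acid	120	73848	77248	64455188
piperacillin/tazobactam	113	36094	77255	64492942
ampicillin/sulbactam	12	5034	77356	64524002
amoxicillin	81	59895	77287	64469141
ampicillin	26	6381	77342	64522655
piperacillin	6	1767	77362	64527269
flucloxacillin	20	3913	77348	64525123
cloxacillin	13	1742	77355	64527294
oxacillin	7	1727	77361	64527309
nafcillin	24	1299	77344	64527737
penicillin v	5	5860	77363	64523176
penicillin g	4	6412	77364	64522624
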