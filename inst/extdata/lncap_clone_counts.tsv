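locus	viral_strand	amplicon	clones	sequenced
K(I)	Rev	LTR	1	8
K(I)	Rev	pro	2	9
K(I)	Rev	env-1	6	8
K(I)	Rev	env-3	5	7
K106	Rev	pro	1	9
K106	Rev	env-2	3	9
K106	Rev	env-3	1	7
K50F	Rev	env-1	2	8
K50F	Rev	env-2	5	9
Fragment_11q12.3	Rev	env-2	1	9
Fragment_11q12.3	Rev	env-3	1	7
K118	Fwd	env-1	10	10
K118	Fwd	env-2	10	10
K118	Fwd	env-3	7	7
Fragment_7q34	Rev	pro	6	9
SoloLTR	Rev	LTR	7	8
SoloLTR	Fwd	LTR	10	10
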