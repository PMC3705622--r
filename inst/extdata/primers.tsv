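name	fwd	rev
unspliced	CTGGTGCATGGAAGATTGGT	CACCGCACTATTGGCCACA
1x-env-1	AGGGAAAAACCGCCTTAGGG	CACCGCACTATTGGCCACA
1x-env-2	TGCGGGCAGCAATACTGCT	CGCACTATTGGCCACACATTC
LTR	CGTGGGAAGGGAAAGACCTGA	AGCAGACAAACATGTGAACAAAGG
pro	CCCCACAAAACCCCCACAG	GATTTCCGCACCCCATTGTTG
env-1	CATGGTAAGCGGGATGTCACT	CACCGCACTATTGGCCACA
env-2	GTGTGGCCAATAGTGCGGT	ATTCCTTTTTCTCCCCATTCCCAG
env-3	GCTGGTGAGAGCAAGAGAGG	CAATGCAACTCCTGCTACAGC
q-env	TCACATGGTAAGCGGGATGTC	CGCACTATTGGCCACACATTC
q-LTR	AGGGAAAAACCGCCTTAGGG	AGCAGACAAACATGTGAACAAAGG
hACTB	CTGGCACCACACCTTCTACA	GCTGGGGTGTTGAAGGTCT
hGAPDH	AGATCATCAGCAATGCCTCCT	AGTCTTCTGGGTGGCAGTG
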