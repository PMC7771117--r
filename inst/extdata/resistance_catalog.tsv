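target	canonical_accession	residue	ref_aa	alt_aa
RyR	AET09964.1	4946	G	E
nAChR-beta1	AFH00994.1	81	R	T
VGSC	AAB47604.1	1014	L	F
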