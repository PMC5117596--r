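ref_id	position	role	expected_residues
PGRPref_synthetic	7	active_site	H
PGRPref_synthetic	15	active_site	Y
PGRPref_synthetic	29	active_site	T
PGRPref_synthetic	33	active_site	H
PGRPref_synthetic	53	active_site	H
PGRPref_synthetic	19	binding_groove	R
PGRPref_synthetic	34	binding_groove	YF
PGRPref_synthetic	46	binding_groove	R
HbA2ref_synthetic	8	sulfide_cysteine	C
HbA2ref_synthetic	35	conserved_disulfide_cysteine	C
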