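junction_aa	v_call	j_call	duplicate_count	donor_id	cohort
CASSVDGNTEAFF	TRBV6-4	TRBJ2-1	3	CD1	CD
CASSLGGAYNEQFF	TRBV6-4	TRBJ2-1	1	CD1	CD
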