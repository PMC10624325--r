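junction_aa	v_call	j_call	duplicate_count	donor_id	cohort
CASSDRDRVNTLYF	TRBV6-4	TRBJ2-1	3	CD2	CD
CASSVDGNTEAFF	TRBV6-4	TRBJ2-1	1	CD2	CD
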