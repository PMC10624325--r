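junction_aa	v_call	j_call	duplicate_count	donor_id	cohort
CASSLAPGATNEKLFF	TRBV6-4	TRBJ2-1	2	HC2	HC
CASSQDRGNQPQHF	TRBV6-4	TRBJ2-1	2	HC2	HC
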