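cell_id	donor_id	cohort	tissue	inflammation	alpha_v_call	alpha_j_call	alpha_cdr3_nt	alpha_cdr3_aa	alpha_productive	beta_v_call	beta_d_call	beta_j_call	beta_cdr3_nt	beta_cdr3_aa	beta_productive
c1	HC1	HC	colon	uninflamed	TRAV1-2	TRAJ33	TGCGCAGTAATGGACAGCAACTACCAACTAATATGG	CAVMDSNYQLIW	TRUE	TRBV20-1	TRBD1	TRBJ2-1	TGCGCAAGCAGCGAAGGACAAGGAGCATACGAACAATACTTC	CASSEGQGAYEQYF	TRUE
c2	HC1	HC	colon	uninflamed	TRAV1-2	TRAJ33	TGCGCAGTAATGGACAGCAACTACCAACTAATATGG	CAVMDSNYQLIW	TRUE	TRBV20-1	TRBD1	TRBJ2-1	TGCGCAAGCAGCGAAGGACAAGGAGCATACGAACAATACTTC	CASSEGQGAYEQYF	TRUE
c3	HC1	HC	colon	uninflamed	TRAV1-2	TRAJ33	TGCGCAGTAATGGACAGCAACTACCAACTAATATGG	CAVMDSNYQLIW	TRUE	TRBV20-1	TRBD1	TRBJ2-1	TGCGCAAGCAGCCTACTATGGGACCAACCACAACACTTC	CASSLLWDQPQHF	TRUE
c4	HC1	HC	colon	uninflamed	TRAV8-2	TRAJ33	TGCGCAGTAATGGACAGCAACTACCAACTAATATGG	CAVMDSNYQLIW	TRUE	TRBV20-1	TRBD1	TRBJ2-1	TGCGCAAGCAGCACAACAAACGAAAAACTATTCTTC	CASSTTNEKLFF	TRUE
c5	HC2	HC	colon	uninflamed	TRAV1-2	TRAJ33	TGCGCAGTAATGGACAGCAACTACCAACTAATATGG	CAVMDSNYQLIW	TRUE	TRBV20-1	TRBD1	TRBJ2-1	TGCGCAAGCAGCCAAGACAGAGGAAACCAACCACAACACTTC	CASSQDRGNQPQHF	TRUE
c6	HC2	HC	colon	uninflamed	TRAV1-2	TRAJ33	TGCGCAGTAATGGACAGCAACTACCAACTAATATGG	CAVMDSNYQLIW	TRUE	TRBV20-1	TRBD1	TRBJ2-1	TGCGCAAGCAGCCTAGCACCAGGAGCAACAAACGAAAAACTATTCTTC	CASSLAPGATNEKLFF	TRUE
d1	CD1	CD	colon	inflamed	TRAV1-2	TRAJ33	TGCGCAGTAATGGACAGCAACTACCAACTAATATGG	CAVMDSNYQLIW	TRUE	TRBV20-1	TRBD1	TRBJ2-1	TGCGCAAGCAGCCTAGGAGGAGCATACAACGAACAATTCTTC	CASSLGGAYNEQFF	TRUE
d2	CD1	CD	colon	inflamed	TRAV1-2	TRAJ33	TGCGCAGTAATGGACAGCAACTACCAACTAATATGG	CAVMDSNYQLIW	TRUE	TRBV20-1	TRBD1	TRBJ2-1	TGCGCAAGCAGCCTAGGAGGAGCATACAACGAACAATTCTTC	CASSLGGAYNEQFF	TRUE
d3	CD1	CD	colon	uninflamed	TRAV1-2	TRAJ33	TGCGCAGTAATGGACAGCAACTACCAACTAATATGG	CAVMDSNYQLIW	TRUE	TRBV20-1	TRBD1	TRBJ2-1	TGCGCAAGCAGCCTAGGAGGAGCATACAACGAACAATTCTTC	CASSLGGAYNEQFF	TRUE
d4	CD1	CD	colon	uninflamed	TRAV1-2	TRAJ33	TGCGCAGTAATGGACAGCAACTACCAACTAATATGG	CAVMDSNYQLIW	TRUE	TRBV20-1	TRBD1	TRBJ2-1	TGCGCAAGCAGCGTAGACGGAAACACAGAAGCATTCTTC	CASSVDGNTEAFF	TRUE
d5	CD2	CD	colon	uninflamed	TRAV1-2	TRAJ33	TGCGCAGTAATGGACAGCAACTACCAACTAATATGG	CAVMDSNYQLIW	TRUE	TRBV20-1	TRBD1	TRBJ2-1	TGCGCAAGCAGCCCAGGAACAAGCGGAAGCTACGAACAATACTTC	CASSPGTSGSYEQYF	TRUE
d6	CD2	CD	colon	inflamed	TRAV1-2	TRAJ33	TGCGCAGTAATGGACAGCAACTACCAACTAATATGG	CAVMDSNYQLIW	TRUE	TRBV20-1	TRBD1	TRBJ2-1	TGCGCAAGCAGCGAAGCAAGAGGATACGGATACACATTC	CASSEARGYGYTF	TRUE
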