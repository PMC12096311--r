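name	value
tyfonas_sub1_start	10406708
tyfonas_sub1_end	10412867
tyfonas_sub1_len_printed	6160
tyfonas_sub2_start	10439305
tyfonas_sub2_end	10439349
tyfonas_sub2_len_printed	45
chr02_sub_bp_start	47848244
chr02_sub_bp_end	47848246
chr02_sub_ref_len_printed	3
chr02_sub_qry_len_printed	504
chr02_ins_pos	47863185
chr02_ins_len_printed	7476
best_f1_relaxed_pct	53.77
best_precision_relaxed_pct	52.22
best_recall_relaxed_pct	65.02
relative_rate_regulatory	1.48
relative_rate_genic	0.97
relative_rate_intergenic	0.74
inv_fwd_identity_pct	99
inv_rev_identity_pct	90
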