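category	group	value
svtype	INS	780
svtype	DEL	619
svtype	INV	13
svtype	SUB	223
svtype_total	printed	1635
scenario	copy_number_discrepancy	2026
scenario	reverse_artifact	87
scenario	copy_misalignment	2129
scenario	combined_complex	290
scenario_total	printed	4532
pattern	unique	720
pattern	cat1	417
pattern	cat2	203
pattern	cat3	295
pattern_repeat_total	printed	915
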