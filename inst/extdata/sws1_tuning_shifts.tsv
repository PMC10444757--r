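# Known lambda_max shifts for SWS1 substitutions, bovine RH1 numbering.
# Intervals [shift_low_nm, shift_high_nm] summarise mutagenesis reports for
# the same or closely analogous switches; pairs absent from this table are
# treated as zero-centred low-confidence intervals by estimate_lambda_max().
site	from	to	shift_low_nm	shift_high_nm
97	S	C	-1	0
116	M	V	-3	0
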