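index	phase	t_stim_s	duration_s	odor	role	side_index	shock_onset_s	shock_dur_s
1	training	30.000	4.000	nonanol	CS-	1	NA	NA
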