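session_id	animal_id	trial_index	block_index	rewarded_side	choice	outcome	t_cue	t_init	t_choice	t_outcome	light_on	light_epoch
s1	m1	1	1	left	left	reward	0	0.9	1.6	2.1	FALSE	na
s1	m1	2	1	left	left	reward	6.2	7.1	7.9	8.4	FALSE	na
s1	m1	3	1	left	right	punish	12.5	13.3	14.0	14.5	FALSE	na
s1	m1	4	1	left	left	none	21.1	22.0	22.8	23.3	FALSE	na
s1	m1	5	1	left	left	reward	27.4	28.2	29.1	29.6	FALSE	na
s2	m1	1	1	right	right	reward	0	1.0	1.8	2.3	TRUE	choice
s2	m1	2	1	right	left	punish	6.5	7.3	8.1	8.6	FALSE	na
s2	m1	3	1	right	right	reward	14.9	15.8	16.5	17.0	TRUE	choice
s2	m1	4	1	right	omission	none	23.2	24.1	NA	NA	FALSE	na
s3	m2	1	1	left	right	punish	0	0.8	1.5	2.0	FALSE	na
s3	m2	2	1	left	left	reward	6.4	7.2	8.0	8.5	FALSE	na
s3	m2	3	1	left	left	none	12.8	13.7	14.4	14.9	FALSE	na
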