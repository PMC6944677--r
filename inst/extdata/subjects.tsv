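# Anthropometrics of the affected matrilineal relatives (in-paper clinical
# summary table, transcribed). obese_duration in years; ">10" kept verbatim.
id	age	sex	height_cm	weight_kg	bmi	obese_duration
III-1	9.3	M	154	60	25.3	4
II-2	38.2	F	165	70	25.7	>10.0
II-4	35.5	F	165	70	25.7	>10.0
III-2	6.3	M	128	40	24.4	1
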