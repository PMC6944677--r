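# DEMO age/sex BMI percentile cutoffs (kg/m^2), illustrative values for
# testing only — not the national reference tables. Age bands are
# half-open [age_min, age_max).
sex	age_min	age_max	p85	p95	p99
M	6	7	15.5	18.0	20.5
M	7	9	16.5	19.5	22.0
M	9	10	18.5	21.0	24.0
M	10	18	19.5	22.5	26.0
F	6	7	15.5	18.0	20.0
F	7	9	16.5	19.0	21.5
F	9	10	18.0	20.5	23.5
F	10	18	19.5	22.5	26.0
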