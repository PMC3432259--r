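# Published group BMS results for the four-region auditory network
# (10 subjects, uniform Dirichlet prior alpha0 = 1 per model). For the
# family comparisons (K = 6) only the winner's Dirichlet parameter was
# published; the losing mass follows from sum(alpha) = N + K.
comparison	K	model	alpha	expected_r	phi
input_stage	2	input_HG	2.6036	0.2170	0.0177
input_stage	2	input_STG	9.3964	0.7830	0.9823
bilinear_family	6	bilinear_all_four	7.8684	0.4918	0.9068
nonlinear_family	6	nonlinear_stg_own	8.0627	0.5039	0.9494
head_to_head	2	nonlinear_stg_own	10.9978	0.9165	0.9995
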