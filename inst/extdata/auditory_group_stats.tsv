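# Published group-level input/connectivity statistics for the four-region
# auditory network (bilateral HG and STG), white-noise listening, 10 subjects.
# p is the value as published (the two-sided Student-t p divided by the 12
# tested connections). The RHG->LSTG mean is stored signed (-0.0011): the
# published table prints the magnitude, but its own t = -0.288 fixes the sign.
source	target	type	mean_hz	P	sd	p	t	highlighted
ext	LSTG	input	0.1356	1.0000	0.1131	3.333e-4	3.791	0
ext	RSTG	input	0.2551	1.0000	0.0950	0.0	8.495	0
LHG	LSTG	coupling	0.0018	0.8138	0.0129	5.617e-2	0.435	0
LHG	RHG	coupling	0.0145	0.8492	0.0250	8.250e-3	1.838	0
LHG	RSTG	coupling	0.0101	0.5235	0.0204	1.275e-2	1.562	0
LSTG	LHG	coupling	0.0973	1.0000	0.0974	1.000e-3	3.158	1
LSTG	RHG	coupling	0.0801	1.0000	0.0856	1.333e-3	2.959	1
LSTG	RSTG	coupling	0.0238	0.5243	0.0321	3.667e-3	2.346	0
RHG	LHG	coupling	0.0199	0.9322	0.0283	4.417e-3	2.231	0
RHG	LSTG	coupling	-0.0011	0.8553	0.0119	6.500e-2	-0.288	0
RHG	RSTG	coupling	0.0042	0.7825	0.0136	2.908e-2	0.988	0
RSTG	LHG	coupling	0.1716	1.0000	0.1432	3.333e-4	3.790	1
RSTG	LSTG	coupling	0.0233	0.9134	0.0395	8.000e-3	1.860	0
RSTG	RHG	coupling	0.1339	1.0000	0.1032	2.500e-4	4.101	1
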