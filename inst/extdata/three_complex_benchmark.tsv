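# Published predictions of five hot-spot predictors on four shared residues of
# one protein (chain A) in three different complexes (PDB 1TH1, 1JPP, 3OUX).
# "observed" is the curated categorical label (Strong = hot spot). robetta_ddg
# and crf_ddg are predicted ddG values in kcal/mol (crf = the contact
# random-forest method implemented by this package, as published for this
# benchmark); hotpoint/kfc2a/kfc2b are published binary calls (1 = hot spot).
complex	residue	observed	robetta_ddg	crf_ddg	hotpoint	kfc2a	kfc2b
1TH1	TRP383	Strong	1.22	1.06	1	0	0
1TH1	ARG386	Insignificant	1.00	2.61	0	1	1
1TH1	LYS435	Insignificant	1.60	1.76	0	0	0
1TH1	HIS470	Insignificant	0.50	2.40	1	1	0
1JPP	TRP383	Intermediate	0.93	0.325	0	0	0
1JPP	ARG386	Strong	0.50	1.65	0	1	1
1JPP	LYS435	Intermediate	0.50	1.12	0	0	0
1JPP	HIS470	Insignificant	0.47	0.99	1	0	0
3OUX	TRP383	Insignificant	2.58	1.87	1	1	1
3OUX	ARG386	Intermediate	2.38	2.38	0	1	1
3OUX	LYS435	Strong	1.69	2.65	0	0	0
3OUX	HIS470	Strong	3.05	3.90	1	1	0
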