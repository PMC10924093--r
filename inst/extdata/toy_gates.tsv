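rsid	p	beta_egfr	beta_bun	p_a	p_b	log2fc	de_p	af_cohort	af_ref	pass_sig	pass_dir	pass_rep	pass_de	af_shortlist	af_signif
r1	4.9e-08	0.02	-0.03	0.01	0.04	1.2	0.001	0.50	0.30	TRUE	TRUE	TRUE	TRUE	TRUE	TRUE
r2	5.1e-08	0.02	0.03	0.01	0.06	0.8	0.002	0.35	0.30	FALSE	FALSE	FALSE	FALSE	FALSE	FALSE
r3	1e-12	0	-0.03	0.06	0.01	-1.0	0.003	0.42	0.30	TRUE	FALSE	FALSE	TRUE	TRUE	FALSE
r4	0.2	-0.01	0.05	0.049	0.049	-0.5	0.004	0.10	0.30	FALSE	TRUE	TRUE	FALSE	TRUE	TRUE
r5	5e-08	-0.01	-0.02	0.05	0.01	2.0	0.005	0.30	0.30	FALSE	FALSE	FALSE	TRUE	FALSE	FALSE
r6	1e-09	0.1	-0.1	0.001	0.001	0.0	0.006	0.45	0.30	TRUE	TRUE	TRUE	FALSE	TRUE	FALSE
r7	0.04	0	0	0.9	0.9	1.0	0.007	0.299	0.30	FALSE	FALSE	FALSE	TRUE	FALSE	FALSE
r8	2e-08	-0.2	0.1	0.02	0.03	-3.0	0.008	0.55	0.30	TRUE	TRUE	TRUE	TRUE	TRUE	TRUE
r9	0.5	0.3	-0.2	0.05	0.05	0.99	0.009	0.39	0.30	FALSE	TRUE	FALSE	FALSE	FALSE	FALSE
r10	3e-10	-0.05	-0.01	0.04	0.001	-1.5	0.010	0.41	0.30	TRUE	FALSE	TRUE	TRUE	TRUE	FALSE
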