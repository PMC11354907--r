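locus	chr	start	stop	n_snps	trait_a	trait_b	rho	r2	p
2351	19	45040933	45893307	375	AD	HDL	-0.29	0.09	3.75e-10
962	6	32208902	32454577	538	AD	LDL	0.64	0.41	1.69e-4
964	6	32539568	32586784	26	AD	LDL	0.34	0.11	1.14e-3
966	6	32629240	32682213	161	AD	LDL	0.76	0.58	1.72e-5
2351	19	45040933	45893307	369	AD	LDL	0.34	0.11	2.21e-100
2351	19	45040933	45893307	371	AD	Triglycerides	0.26	0.07	1.02e-4
964	6	32539568	32586784	26	AD	Total_cholesterol	0.41	0.17	1.22e-3
966	6	32629240	32682213	161	AD	Total_cholesterol	0.51	0.26	3.85e-4
1351	8	125453323	126766827	1102	AD	Total_cholesterol	0.30	0.09	1.04e-79
2351	19	45040933	45893307	373	AD	Total_cholesterol	0.38	0.14	3.86e-9
965	6	32586785	32629239	651	AD	Angina_pectoris	0.34	0.12	2.69e-4
2351	19	45040933	45893307	2620	AD	Angina_pectoris	0.37	0.14	1.29e-10
963	6	32454578	32539567	89	AD	Cardiac_dysrhythmias	-0.38	0.14	7.25e-6
2351	19	45040933	45893307	2620	AD	Coronary_arteriosclerosis	0.53	0.28	9.80e-28
2209	17	45883902	47516224	4658	AD	Ischemic_heart_disease	0.33	0.11	1.28e-3
2351	19	45040933	45893307	2620	AD	Ischemic_heart_disease	0.44	0.19	6.70e-17
964	6	32539568	32586784	496	AD	Myocardial_infarction	0.41	0.16	8.95e-4
2351	19	45040933	45893307	2620	AD	Myocardial_infarction	0.45	0.20	3.37e-14
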