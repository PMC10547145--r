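stage	trait	environment	test	model	null_loglik	alt_loglik	reference	printed_lrt	printed_p
stage1	FRS-08	EDU	overall_gxe	full	-547.8467	-542.6951	mix_chisq_2_3	10.303	0.01
stage1	FRS-08	INC	overall_gxe	full	-470.1946	-468.5453	mix_chisq_2_3	3.2985	0.27
stage1	FRS-08	SEI	overall_gxe	full	-531.3359	-531.0487	mix_chisq_2_3	0.5744	0.83
stage1	PCE-AA	EDU	overall_gxe	full	-544.9318	-534.6063	mix_chisq_2_3	20.6511	7.9E-05
stage1	PCE-AA	INC	overall_gxe	full	-475.9489	-473.3829	mix_chisq_2_3	5.1319	0.11
stage1	PCE-AA	SEI	overall_gxe	full	-535.4172	-534.9308	mix_chisq_2_3	0.9728	0.71
stage1	PCE-CA	EDU	overall_gxe	full	-558.9761	-554.3081	mix_chisq_2_3	9.3361	0.02
stage1	PCE-CA	INC	overall_gxe	full	-493.6883	-492.9215	mix_chisq_2_3	1.5337	0.46
stage1	PCE-CA	SEI	overall_gxe	full	-549.9187	-549.0324	mix_chisq_2_3	1.7724	0.52
stage1	CCA-IMT	EDU	overall_gxe	full	-272.8105	-261.4156	mix_chisq_2_3	22.7900	2.8E-05
stage1	CCA-IMT	INC	overall_gxe	full	-261.2915	-259.1017	mix_chisq_2_3	4.3797	0.17
stage1	CCA-IMT	SEI	overall_gxe	full	-269.7903	-268.7363	mix_chisq_2_3	2.1078	0.45
stage1	CCA-FIMT	EDU	overall_gxe	full	-276.8565	-272.4017	mix_chisq_2_3	8.9098	0.02
stage1	CCA-FIMT	INC	overall_gxe	full	-258.6960	-256.2971	mix_chisq_2_3	4.7978	0.14
stage1	CCA-FIMT	SEI	overall_gxe	full	-270.5050	-269.4054	mix_chisq_2_3	2.1992	0.43
stage1	ICA-IMT	EDU	overall_gxe	full	-265.9061	-254.1646	mix_chisq_2_3	23.4829	2.0E-05
stage1	ICA-IMT	INC	overall_gxe	full	-256.1566	-255.8131	mix_chisq_2_3	0.6870	0.79
stage1	ICA-IMT	SEI	overall_gxe	full	-261.3151	-260.7885	mix_chisq_2_3	1.0533	0.69
stage1	ICA-FIMT	EDU	overall_gxe	full	-254.5134	-236.9297	mix_chisq_2_3	35.1676	6.8E-08
stage1	ICA-FIMT	INC	overall_gxe	full	-243.4058	-243.2240	mix_chisq_2_3	0.3634	0.89
stage1	ICA-FIMT	SEI	overall_gxe	full	-249.0360	-248.7515	mix_chisq_2_3	0.5691	0.83
stage2	FRS-08	EDU	genetic_correlation	reduced	-544.5313	-542.9009	mix_point0_chisq_1	3.2609	0.0355
stage2	FRS-08	EDU	environmental_variance	reduced	-546.3321	-542.9009	chisq_1	6.8624	0.0088
stage2	PCE-AA	EDU	genetic_variance	full	-538.4800	-534.6063	chisq_1	7.7474	0.0054
stage2	PCE-AA	EDU	genetic_correlation	full	-535.8287	-534.6063	mix_point0_chisq_1	2.4448	0.0590
stage2	PCE-AA	EDU	environmental_variance	full	-539.1379	-534.6063	chisq_1	9.0632	0.0026
stage2	PCE-CA	EDU	genetic_variance	full	-554.3091	-554.3081	chisq_1	0.0021	0.9633
stage2	PCE-CA	EDU	genetic_correlation	full	-557.7770	-554.3081	mix_point0_chisq_1	6.9378	0.0042
stage2	PCE-CA	EDU	environmental_variance	full	-554.5175	-554.3081	chisq_1	0.4188	0.5175
stage2	CCA-IMT	EDU	genetic_variance	full	-261.5265	-261.4156	chisq_1	0.2219	0.6376
stage2	CCA-IMT	EDU	genetic_correlation	full	-270.2954	-261.4156	mix_point0_chisq_1	17.7596	1.3E-05
stage2	CCA-IMT	EDU	environmental_variance	full	-264.1498	-261.4156	chisq_1	5.4686	0.0194
stage2	CCA-FIMT	EDU	genetic_variance	full	-274.2249	-272.4017	chisq_1	3.6466	0.0562
stage2	CCA-FIMT	EDU	genetic_correlation	full	-273.5546	-272.4017	mix_point0_chisq_1	2.3059	0.0644
stage2	CCA-FIMT	EDU	environmental_variance	full	-274.1815	-272.4017	chisq_1	3.5597	0.0592
stage2	ICA-IMT	EDU	genetic_variance	full	-257.9995	-254.1646	chisq_1	7.6697	0.0056
stage2	ICA-IMT	EDU	genetic_correlation	full	-256.3332	-254.1646	mix_point0_chisq_1	4.3370	0.0186
stage2	ICA-IMT	EDU	environmental_variance	full	-262.0594	-254.1646	chisq_1	15.7894	7.1E-05
stage2	ICA-FIMT	EDU	genetic_variance	full	-243.8484	-236.9297	chisq_1	13.8375	0.0002
stage2	ICA-FIMT	EDU	genetic_correlation	full	-240.0164	-236.9297	mix_point0_chisq_1	6.17357	0.0065
stage2	ICA-FIMT	EDU	environmental_variance	full	-248.9148	-236.9297	chisq_1	23.9702	9.8E-07
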