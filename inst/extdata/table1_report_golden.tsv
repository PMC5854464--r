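step	class	theoretical_pct	fraction	n_sublines	mean_pct	sd_pct	statistic	df	p_value
F3	mCe	50	1/2	6	49.2	3.9	-0.491158	5	0.644112
F3	mCe+mO+mC	50	1/2	6	50.8	3.9	0.491158	5	0.644112
F4		25	1/4	6	23.9	7.2	-0.376265	5	0.722157
F4	mCe	25	1/4	6	30.8	8.5	1.652362	5	0.15937
F4	mO	12.5	1/8	6	12.9	5.6	0.188114	5	0.858184
F4	mC	12.5	1/8	6	9.5	2.1	-3.420043	5	0.018837
F4	mCe+mO	12.5	1/8	6	9.9	6.3	-1.003254	5	0.36179
F4	mCe+mC	12.5	1/8	6	11.8	4.2	-0.415274	5	0.69516
F4	mO+mC	NA	NA	6	0.5	1.2	NA	NA	NA
F4	mCe+mO+mC	NA	NA	6	0.7	1.6	NA	NA	NA
F5		25	1/4	6	25.8	3.5	0.538832	5	0.613118
F5	mO	25	1/4	6	28.1	3.5	2.170636	5	0.082077
F5	mC	25	1/4	6	22.2	8.8	-0.775919	5	0.472883
F5	mO+mC	25	1/4	6	23.9	4	-0.662541	5	0.536939
F6-S	mO	50	1/2	6	52.1	3.7	1.383282	5	0.225157
F6-S	mC	50	1/2	6	47.9	3.7	-1.383282	5	0.225157
F6	mO	25	1/4	6	20.7	1.9	-5.525667	5	0.00266
F6	mC	25	1/4	6	26.9	5.2	0.883217	5	0.417556
F6	mO+mC	50	1/2	6	52.5	4.9	1.236981	5	0.271021
F7-O	mO	100	1	6	100	0	0	5	1
F7-C	mC	100	1	6	100	0	0	5	1
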