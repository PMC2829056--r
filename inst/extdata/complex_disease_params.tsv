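# Published genetic-epidemiology parameters for 17 complex diseases
# (19 rows: two independent estimates each for bipolar disorder and
# schizophrenia). Prevalence is printed as a percentage (K x 100);
# lambda_s is the sibling recurrence risk ratio.
name	prevalence_percent	lambda_s
Age-related macular degeneration	11.8	2.2
Unipolar disorder	10	1.7
Coronary artery disease	5.6	3.2
Breast cancer	3.6	2.5
Type-II diabetes	3	3.5
Prostate cancer	2.4	2.8
Asthma	2	2.6
Lung cancer	1.7	6.1
Colon cancer	1.5	5.1
Bladder cancer	1	1.7
Stomach cancer	1	6
Bipolar disorder	1	6.8
Bipolar disorder (twin registry)	0.45	7.9
Schizophrenia	0.85	8.6
Schizophrenia (twin registry)	0.4	9
Rheumatoid arthritis	0.75	8
Type-I diabetes	0.54	13.7
Crohn's disease	0.1	26
Systemic lupus erythematosus	0.03	30
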