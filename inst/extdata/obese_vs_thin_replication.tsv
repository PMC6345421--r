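# Discovery and UKBB replication odds ratios (obese vs thin, thin as
# reference) for three BMI-tail association signals; effect allele is the
# BMI-increasing allele. Positions hg19.
snp_id	study	effect_allele	other_allele	or	ci_low	ci_high	p
rs62107261	discovery	T	C	2.37	1.75	3.20	2.07E-08
rs62107261	UKBB	T	C	1.54	1.35	1.76	3.57E-10
rs75398113	discovery	C	A	1.53	1.27	1.85	8.91E-06
rs75398113	UKBB	C	A	1.24	1.12	1.37	2.07E-05
rs13135092	discovery	G	A	1.58	1.30	1.93	4.70E-06
rs13135092	UKBB	G	A	1.25	1.12	1.39	5.57E-05
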