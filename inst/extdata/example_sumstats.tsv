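# Example per-locus association summary statistics (obese vs thin, thin as
# reference); combined OR(95%CI) cells and both scientific-notation
# dialects are accepted by the reader.
snp_id	chr	pos	effect_allele	other_allele	eaf_group1	eaf_group0	or_ci	p
rs9930333	16	53799977	G	T	0.4959	0.3746	1.70(1.52,1.90)	2.30x10^-20
rs2168711	18	57848531	C	T	0.2890	0.1995	1.66(1.45,1.89)	8.29E-14
rs62107261	2	422144	T	C	0.9637	0.9338	2.37(1.75,3.20)	2.07E-08
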