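gene	class	genotype	mean_gfp	mean_all	q
ins-17	insulin-family peptide	wt	265.6	34.4	2.37e-06
flp-14	FLP-family peptide	wt	19547.2	2917.5	7.55e-08
nlp-34	NLP-family peptide	wt	67.0	9.8	0.01
ins-17	insulin-family peptide	mut	101.7	56.0	0.72
flp-14	FLP-family peptide	mut	8562.1	3427.3	0.53
nlp-34	NLP-family peptide	mut	37.8	13.3	0.67
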