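gene	protein_position	ref_aa	alt_aa	variant_id	allele_frequency
TP53	72	P	A	rs587782769	0.0000040
TP53	72	P	A	rs1042522	0.6629
TP53	73	P	A	syn_tp53_73	0.0010
CRBN	112	R	Q	syn_crbn_112	0.0000120
SALL4	34	T	M	syn_sall4_34	0.0001000
SALL4	210	A	V	syn_sall4_210	0.0002000
RECQL4	88	G	S	syn_recql4_88	0.0000500
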