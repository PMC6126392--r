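protein_accession	d_score
P_CONT	0.1
P_REV	0.1
P_MISS	0.1
P_TWOK	0.1
P_ARG	0.55
P_FEW	0.6
P_NOLATE	0.3
P_IMP	0.7
P_ART	0.12
P_SEC	0.92
P_LEAK	0.08
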