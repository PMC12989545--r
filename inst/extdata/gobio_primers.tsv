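name	assay	direction	sequence
GoBio_Xoxf_f	xoxF	forward	GGTCGAGCTTGGGATCGTAG
GoBio_Xoxf_r	xoxF	reverse	GAAGAAGGGCGAGACCAACA
GoBio_CopG_f	copG	forward	TCATCACCCAAGCCAACCAG
GoBio_CopG_r	copG	reverse	TCATGGTCGATCCGTCCTCT
GoBio_Ubik_f	ubik	forward	GTTCATCGCCCTTGAGGTAG
GoBio_Ubik_r	ubik	reverse	GTTCCTTGCGAATGCGGG
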