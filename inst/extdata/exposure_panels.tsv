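source_label	cohort	platform	n_samples	n_proteins_assayed	n_proteins_instrumented
ukbppp	UK Biobank Pharma Proteomics Project	Olink	54219	2923	2112
decode	deCODE Health study	SomaScan	35559	4907	1970
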