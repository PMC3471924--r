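gene_function	overlap	list_size
TGFb_responsive	144	313
MG_development	89	313
Breast_cancer_associated	41	313
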