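class	carriers_expressed	carriers_masked	n_expressed	n_masked
premature_stop_snp	2	38	226	564
active_site_mutation	1	14	226	564
gene_deletion	2	31	226	564
unidentified_lesion	6	NA	226	564
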