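quantity	species	recovered	eligible
orthology_sensitivity	chicken	11206	12856
orthology_sensitivity	pig	14381	16844
orthology_precision	chicken	12582	14603
orthology_precision	pig	16934	18584
feelnc_reference_lnc_agreement	chicken	7429	8446
feelnc_reference_lnc_agreement	pig	8008	8977
atlas_overlap_lnc_transcripts	chicken	20257	41026
atlas_overlap_lnc_genes	chicken	6986	14872
atlas_overlap_unknown_lnc_transcripts	chicken	11991	32760
atlas_overlap_unknown_lnc_genes	chicken	2551	10437
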