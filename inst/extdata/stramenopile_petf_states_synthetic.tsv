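taxon	state
Thalassiosira_oceanica_CCMP1005	absent
Thalassiosira_pseudonana	present
Phaeodactylum_tricornutum	present
Fragilariopsis_cylindrus	present
Triparma_laevis	present
Aureococcus_anophagefferens	absent
Aureoumbra_lagunensis	absent
Dictyocha_speculum	present
Pleurocladia_lacustris	absent
Ectocarpus_siliculosus	present
Fucus_vesiculosus	present
Saccharina_japonica	present
Vaucheria_litorea	present
Nannochloropsis_gaditana	present
Heterosigma_akashiwo	present
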