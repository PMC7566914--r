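((((Thalassiosira_oceanica_CCMP1005,Thalassiosira_pseudonana),(Phaeodactylum_tricornutum,Fragilariopsis_cylindrus)),Triparma_laevis),((Aureococcus_anophagefferens,Aureoumbra_lagunensis),Dictyocha_speculum),(((Pleurocladia_lacustris,Ectocarpus_siliculosus),(Fucus_vesiculosus,Saccharina_japonica)),(Vaucheria_litorea,Nannochloropsis_gaditana)),Heterosigma_akashiwo);
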