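# Kidney renal clear cell carcinoma profile: identical to the default
# except for the relaxed methylation-network hub threshold (degree > 10).
analysis:
  preprocess:
    min_expressed_fraction: 0.5
    presence_threshold: 0
    ppi_min_confidence: 500
  significance:
    pearson_alpha: 0.01
    partial_alpha: 0.05
  diff_network:
    meth_score_threshold: 0.7
  ranking:
    diff_pcorn_min_degree: 30
    diff_mn_min_degree: 10
    top_k: 15
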