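# Forward causal scenario: 100 exposure SNPs jointly explaining ~2% of the
# exposure variance, true causal OR 1.05 per exposure unit, moderate
# confounding, plus 24 independent outcome-trait risk loci (log-odds
# 0.08-0.18 per allele) available as reverse-direction instruments.
n_individuals: 20000
n_exposure_snps: 100
n_outcome_snps: 24
h2_exposure: 0.02
exposure_mean: 27
exposure_total_sd: 4.8
confounder_effect_x: 1.0
confounder_effect_y: 0.3
causal_or: 1.05
prevalence: 0.05
pleiotropy_per_allele: 0
pleiotropy_balanced: false
reverse_beta: 0
outcome_snp_logodds_min: 0.08
outcome_snp_logodds_max: 0.18
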