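# No causal effect but a shared confounder drives both traits: ordinary
# logistic regression of outcome on exposure is biased away from the null
# while valid MR is null-centred.
n_individuals: 10000
n_exposure_snps: 100
n_outcome_snps: 0
h2_exposure: 0.02
exposure_mean: 27
exposure_total_sd: 4.8
confounder_effect_x: 1.0
confounder_effect_y: 0.5
causal_or: 1.0
prevalence: 0.05
pleiotropy_per_allele: 0
pleiotropy_balanced: false
reverse_beta: 0
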