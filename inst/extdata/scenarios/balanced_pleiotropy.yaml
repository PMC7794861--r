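# Direct SNP-outcome effects of +/-0.05 log-odds per allele alternating in
# sign (balanced pleiotropy, mean zero): extra heterogeneity but no
# directional bias; the Egger intercept test should stay near its nominal
# size.
n_individuals: 50000
n_exposure_snps: 100
n_outcome_snps: 0
h2_exposure: 0.10
gamma_rel_min: 0.5
gamma_rel_max: 1.5
exposure_mean: 27
exposure_total_sd: 4.8
confounder_effect_x: 0
confounder_effect_y: 0
causal_or: 1.05
prevalence: 0.05
pleiotropy_per_allele: 0.05
pleiotropy_balanced: true
reverse_beta: 0
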