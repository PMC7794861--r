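# Reverse causation only: 24 outcome-trait risk loci, no SNP-exposure
# effects, no forward causal path; cases gain reverse_beta exposure units
# (kg/m^2) after the outcome draw.
n_individuals: 20000
n_exposure_snps: 0
n_outcome_snps: 24
h2_exposure: 0
exposure_mean: 27
exposure_total_sd: 4.8
confounder_effect_x: 1.0
confounder_effect_y: 0.3
causal_or: 1.0
prevalence: 0.05
pleiotropy_per_allele: 0
pleiotropy_balanced: false
reverse_beta: 1.0
outcome_snp_logodds_min: 0.08
outcome_snp_logodds_max: 0.18
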