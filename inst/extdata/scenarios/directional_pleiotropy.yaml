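# Every exposure SNP also affects the outcome directly by +0.05 log-odds
# per allele (directional pleiotropy): IVW is biased upward, the MR-Egger
# intercept estimates the common direct effect. Instruments are individually
# strong (per-SNP F > 10: 100 SNPs explaining 10% of exposure variance at
# n = 50,000, per-allele effects within a factor 3 of each other) so the
# Egger orientation convention is sign-stable.
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
pleiotropy_balanced: false
reverse_beta: 0
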