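# Small fixtures built in code for the unit tests.

# harmonized set with known per-SNP effects and standard errors
make_harmonized <- function(gamma, se_gamma, Gamma, se_Gamma,
                            ids = sprintf("snp_%04d", seq_along(gamma))) {
  out <- tibble::tibble(
    variant_id = ids,
    effect_allele = "A", other_allele = "G",
    beta_exp = gamma, se_exp = se_gamma,
    beta_out = Gamma, se_out = se_Gamma,
    eaf_exp = 0.3, eaf_out = 0.3
  )
  class(out) <- c("mr_harmonized", class(out))
  out
}

# random harmonized set under a linear model Gamma = slope * gamma (+ noise)
random_harmonized <- function(J, slope = 0.05, noise = 0, seed = 1) {
  set.seed(seed)
  gamma <- runif(J, 0.02, 0.2)
  se_gamma <- runif(J, 0.005, 0.02)
  se_Gamma <- runif(J, 0.02, 0.08)
  Gamma <- slope * gamma + rnorm(J, sd = noise)
  make_harmonized(gamma, se_gamma, Gamma, se_Gamma)
}

# minimal valid summary-stat tibble
make_sumstats <- function(n = 3, beta = 0.1, se = 0.02,
                          ea = "A", oa = "G", eaf = 0.3) {
  tibble::tibble(
    variant_id = sprintf("snp_%04d", seq_len(n)),
    effect_allele = rep_len(ea, n), other_allele = rep_len(oa, n),
    eaf = rep_len(eaf, n), beta = rep_len(beta, n), se = rep_len(se, n),
    pvalue = 0.01, n = 1000L
  )
}

# tiny scenario for fast pipeline tests
tiny_config <- function(n = 1500, seed = NULL) {
  mr_scenario("forward_causal", n_individuals = n, seed = seed,
              overrides = list(n_exposure_snps = 30L, n_outcome_snps = 8L))
}
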