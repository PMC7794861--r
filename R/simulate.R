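# Synthetic cohort generation under the MR causal diagram:
#   G -> X (per-allele effects gamma), U -> X and U -> logit(Y) (confounding),
#   X -> logit(Y) (causal_beta), G -> logit(Y) directly (pleiotropy),
#   and optionally Y -> X (reverse causation, an additive shift for cases).

#' Simulation configuration for a genotype-exposure-outcome cohort
#'
#' Defines the data-generating model used throughout the package's simulation
#' studies. Genotypes are independent biallelic SNPs in Hardy-Weinberg
#' equilibrium; the exposure is continuous (BMI scale, kg/m^2); the outcome is
#' binary with log-odds linear in the exposure, a standard-normal confounder
#' and any direct (pleiotropic) SNP effects.
#'
#' @param n_individuals Cohort size (>= 1).
#' @param maf Vector of effect-allele frequencies, each in (0, 0.5].
#' @param gamma Per-allele effects on the exposure (exposure units per allele);
#'   same length as `maf`.
#' @param exposure_mean Population mean of the exposure.
#' @param exposure_sd Residual standard deviation of the exposure, after the
#'   genetic and confounder contributions.
#' @param confounder_effect_x Exposure units per unit of the standard-normal
#'   confounder.
#' @param confounder_effect_y Outcome log-odds per unit of the confounder.
#' @param causal_beta Outcome log-odds per exposure unit (the causal effect).
#' @param baseline_logodds Intercept of the outcome logistic model.
#' @param pleiotropy Direct per-allele log-odds effects on the outcome
#'   (default all zero: the exclusion restriction holds by construction when
#'   `pleiotropy` is zero and `reverse_beta` is zero).
#' @param reverse_beta Exposure units added to cases after the outcome draw
#'   (reverse causation; default 0).
#' @param instruments_exposure,instruments_outcome Integer indices of the SNPs
#'   to be used as instruments for the exposure / for the outcome trait.
#'   Default: SNPs with nonzero `gamma` / SNPs with nonzero `pleiotropy` and
#'   zero `gamma`.
#' @param seed Optional integer seed used by [simulate_cohort()].
#'
#' @return A list of class `sim_config`.
#' @seealso [mr_scenario()] for named presets, [simulate_cohort()].
#' @export
sim_config <- function(n_individuals, maf, gamma,
                       exposure_mean = 27, exposure_sd = 4.5,
                       confounder_effect_x = 0, confounder_effect_y = 0,
                       causal_beta = 0, baseline_logodds = qlogis(0.05),
                       pleiotropy = rep(0, length(maf)),
                       reverse_beta = 0,
                       instruments_exposure = NULL,
                       instruments_outcome = NULL,
                       seed = NULL) {
  n_snps <- length(maf)
  if (length(n_individuals) != 1 || n_individuals < 1) {
    abort("`n_individuals` must be a single count >= 1.")
  }
  if (n_snps < 1 || any(maf <= 0) || any(maf > 0.5)) {
    abort("all `maf` must lie in (0, 0.5].")
  }
  if (length(gamma) != n_snps || length(pleiotropy) != n_snps) {
    abort("`gamma` and `pleiotropy` must have the same length as `maf`.")
  }
  if (exposure_sd <= 0) abort("`exposure_sd` must be positive.")
  instruments_exposure <- instruments_exposure %||% which(gamma != 0)
  instruments_outcome <- instruments_outcome %||%
    which(pleiotropy != 0 & gamma == 0)
  cfg <- list(
    n_individuals = as.integer(n_individuals), n_snps = n_snps,
    maf = maf, gamma = gamma,
    exposure_mean = exposure_mean, exposure_sd = exposure_sd,
    confounder_effect_x = confounder_effect_x,
    confounder_effect_y = confounder_effect_y,
    causal_beta = causal_beta, baseline_logodds = baseline_logodds,
    pleiotropy = pleiotropy, reverse_beta = reverse_beta,
    instruments_exposure = as.integer(instruments_exposure),
    instruments_outcome = as.integer(instruments_outcome),
    seed = seed
  )
  # degenerate outcome model: expected prevalence at the centre of the
  # exposure distribution must be strictly inside (0, 1)
  eta0 <- baseline_logodds + causal_beta * exposure_mean +
    sum(pleiotropy * 2 * maf)
  p0 <- plogis(eta0)
  if (p0 <= .Machine$double.eps || p0 >= 1 - .Machine$double.eps) {
    abort("implied outcome prevalence at the intercept is 0 or 1; adjust `baseline_logodds`.")
  }
  structure(cfg, class = "sim_config")
}

#' Named simulation scenario presets
#'
#' Returns a ready-made [sim_config()] for one of the causal scenarios used in
#' the package's simulation studies. Scenario parameters are read from flat
#' key-value YAML files shipped under `inst/extdata/scenarios/` and expanded
#' into per-SNP vectors deterministically: allele frequencies evenly spaced in
#' \[0.1, 0.5\], relative exposure effects evenly spaced in \[0.2, 1.8\] and
#' scaled so the SNPs jointly explain the target fraction of exposure
#' variance, and outcome-SNP log-odds effects evenly spaced over the stated
#' range (emulating published risk loci for a binary trait).
#'
#' Available presets: `"null"`, `"forward_causal"`, `"confounded_null"`,
#' `"directional_pleiotropy"`, `"balanced_pleiotropy"`, `"reverse_causal"`.
#'
#' @param name Scenario name (see above).
#' @param n_individuals Optional override of the preset cohort size.
#' @param seed Optional seed stored in the configuration.
#' @param overrides Named list of further raw preset fields to override
#'   (e.g. `list(h2_exposure = 0.01)`).
#'
#' @return A `sim_config`.
#' @export
mr_scenario <- function(name, n_individuals = NULL, seed = NULL,
                        overrides = list()) {
  path <- system.file("extdata", "scenarios", paste0(name, ".yaml"),
                      package = "grsmr")
  if (!nzchar(path)) {
    abort(paste0("unknown scenario '", name, "'."))
  }
  raw <- yaml::read_yaml(path)
  raw <- modifyList(raw, overrides)
  if (!is.null(n_individuals)) raw$n_individuals <- n_individuals

  jx <- raw$n_exposure_snps %||% 0L
  jo <- raw$n_outcome_snps %||% 0L
  total_var <- raw$exposure_total_sd^2
  maf <- numeric(0); gamma <- numeric(0); pleio <- numeric(0)
  if (jx > 0) {
    maf_x <- seq(0.1, 0.5, length.out = jx)
    rel <- seq(raw$gamma_rel_max %||% 1.8, raw$gamma_rel_min %||% 0.2,
               length.out = jx)
    scale <- sqrt(raw$h2_exposure * total_var /
                    sum(rel^2 * 2 * maf_x * (1 - maf_x)))
    gamma_x <- rel * scale
    pleio_x <- rep(0, jx)
    if (!is.null(raw$pleiotropy_per_allele) && raw$pleiotropy_per_allele != 0) {
      pp <- raw$pleiotropy_per_allele
      pleio_x <- if (isTRUE(raw$pleiotropy_balanced)) {
        pp * rep_len(c(1, -1), jx)
      } else {
        rep(pp, jx)
      }
    }
    maf <- c(maf, maf_x); gamma <- c(gamma, gamma_x); pleio <- c(pleio, pleio_x)
  }
  if (jo > 0) {
    maf_o <- seq(0.15, 0.45, length.out = jo)
    alpha <- seq(raw$outcome_snp_logodds_min, raw$outcome_snp_logodds_max,
                 length.out = jo)
    maf <- c(maf, maf_o); gamma <- c(gamma, rep(0, jo)); pleio <- c(pleio, alpha)
  }
  resid_var <- total_var * (1 - (raw$h2_exposure %||% 0)) -
    raw$confounder_effect_x^2
  if (resid_var <= 0) abort("exposure variance components exceed the total variance.")
  causal_beta <- log(raw$causal_or)
  baseline <- qlogis(raw$prevalence) - causal_beta * raw$exposure_mean -
    sum(pleio * 2 * maf)
  sim_config(
    n_individuals = raw$n_individuals, maf = maf, gamma = gamma,
    exposure_mean = raw$exposure_mean, exposure_sd = sqrt(resid_var),
    confounder_effect_x = raw$confounder_effect_x,
    confounder_effect_y = raw$confounder_effect_y,
    causal_beta = causal_beta, baseline_logodds = baseline,
    pleiotropy = pleio, reverse_beta = raw$reverse_beta %||% 0,
    instruments_exposure = if (jx > 0) seq_len(jx) else integer(0),
    instruments_outcome = if (jo > 0) jx + seq_len(jo) else integer(0),
    seed = seed
  )
}

#' Simulate unlinked biallelic genotypes
#'
#' Draws an `n` x `length(maf)` additive genotype matrix with entries in
#' \{0, 1, 2\}, each column independently Binomial(2, maf) (Hardy-Weinberg).
#'
#' @param n Number of individuals (>= 1).
#' @param maf Effect-allele frequencies in (0, 0.5].
#' @param seed Optional seed.
#' @return Integer matrix with columns named `snp_0001`, ...
#' @export
simulate_genotypes <- function(n, maf, seed = NULL) {
  if (length(n) != 1 || n < 1) abort("`n` must be a single count >= 1.")
  if (any(maf <= 0) || any(maf > 0.5)) abort("all `maf` must lie in (0, 0.5].")
  if (!is.null(seed)) set.seed(seed)
  J <- length(maf)
  G <- matrix(as.double(rbinom(n * J, size = 2L, prob = rep(maf, each = n))),
              nrow = n, ncol = J)
  colnames(G) <- sprintf("snp_%04d", seq_len(J))
  G
}

# deterministic non-palindromic allele pair per SNP index
snp_alleles <- function(j) {
  pairs <- matrix(c("A", "G", "C", "T", "A", "C", "G", "T"),
                  ncol = 2, byrow = TRUE)
  pairs[((j - 1) %% 4) + 1, , drop = FALSE]
}

#' Simulate an individual-level cohort
#'
#' Generates genotypes, a standard-normal confounder `U`, the exposure
#' `x_i = mean + sum_j gamma_j g_ij + confounder_effect_x * U_i + eps_i`,
#' and a Bernoulli outcome with
#' `logit P(y=1) = baseline_logodds + causal_beta * x + confounder_effect_y * U
#'  + sum_j pleiotropy_j g_ij`. When `reverse_beta != 0` the exposure is
#' shifted by `reverse_beta` for cases after the outcome draw.
#'
#' @param config A [sim_config()].
#' @param seed Optional seed overriding `config$seed`.
#' @return A list of class `mr_cohort` with elements `genotypes` (matrix),
#'   `data` (tibble: `exposure`, `outcome`, `confounder`), `snp_info` (tibble
#'   of per-SNP truth: alleles, maf, gamma, pleiotropy, role) and `config`.
#' @export
simulate_cohort <- function(config, seed = NULL) {
  stopifnot(inherits(config, "sim_config"))
  seed <- seed %||% config$seed
  if (!is.null(seed)) set.seed(seed)
  n <- config$n_individuals
  G <- simulate_genotypes(n, config$maf)
  U <- rnorm(n)
  eps <- rnorm(n, sd = config$exposure_sd)
  x <- config$exposure_mean + drop(G %*% config$gamma) +
    config$confounder_effect_x * U + eps
  eta <- config$baseline_logodds + config$causal_beta * x +
    config$confounder_effect_y * U + drop(G %*% config$pleiotropy)
  y <- rbinom(n, 1L, plogis(eta))
  if (config$reverse_beta != 0) {
    x <- x + config$reverse_beta * y
  }
  prev <- mean(y)
  if (prev < 0.001) {
    warn(sprintf("simulated outcome prevalence is %.4f (< 0.1%%).", prev))
  }
  alleles <- do.call(rbind, lapply(seq_len(config$n_snps), snp_alleles))
  role <- rep("none", config$n_snps)
  role[config$instruments_exposure] <- "exposure_instrument"
  role[config$instruments_outcome] <- "outcome_instrument"
  snp_info <- tibble::tibble(
    variant_id = colnames(G),
    effect_allele = alleles[, 1], other_allele = alleles[, 2],
    maf = config$maf, gamma = config$gamma, pleiotropy = config$pleiotropy,
    role = role
  )
  structure(
    list(
      genotypes = G,
      data = tibble::tibble(exposure = x, outcome = y, confounder = U),
      snp_info = snp_info,
      config = config
    ),
    class = "mr_cohort"
  )
}

#' Per-SNP GWAS summary statistics from a cohort
#'
#' Computes marginal per-allele effects: simple linear regression of the
#' exposure on allele count, or univariable logistic regression of the binary
#' outcome (log-odds scale). Monomorphic SNPs are retained but flagged with a
#' missing standard error so downstream harmonization excludes them with an
#' explicit reason rather than silently.
#'
#' @param cohort An `mr_cohort`.
#' @param trait `"exposure"` (linear) or `"outcome"` (logistic).
#' @param snps Optional integer/character subset of SNPs to scan.
#' @return A summary-statistics tibble with columns `variant_id`,
#'   `effect_allele`, `other_allele`, `eaf`, `beta`, `se`, `pvalue`, `n`, and
#'   a logical `monomorphic` flag.
#' @export
cohort_to_summary_stats <- function(cohort, trait = c("exposure", "outcome"),
                                    snps = NULL) {
  stopifnot(inherits(cohort, "mr_cohort"))
  trait <- match.arg(trait)
  G <- cohort$genotypes
  if (!is.null(snps)) G <- G[, snps, drop = FALSE]
  n <- nrow(G)
  if (n < 3) abort("need at least 3 individuals for summary statistics.")
  if (trait == "exposure") {
    y <- cohort$data$exposure
    scan <- linear_scan(G, y)
  } else {
    y <- cohort$data$outcome
    if (length(unique(y)) < 2) {
      abort("outcome must contain both cases and controls.")
    }
    scan <- logistic_scan(G, y)
  }
  info <- cohort$snp_info[match(colnames(G), cohort$snp_info$variant_id), ]
  tibble::tibble(
    variant_id = colnames(G),
    effect_allele = info$effect_allele,
    other_allele = info$other_allele,
    eaf = colMeans(G) / 2,
    beta = scan$beta, se = scan$se, pvalue = scan$pvalue,
    n = n, monomorphic = scan$monomorphic
  )
}

#' Expected reverse-direction effect implied by a configuration
#'
#' For a scenario with reverse causation (cases shifted by `reverse_beta`
#' exposure units), the per-unit-log-odds effect of the binary trait on the
#' exposure implied by the generator is `reverse_beta * E[p_i (1 - p_i)]`,
#' the average logistic derivative over the cohort. Computed by Monte Carlo
#' with a large reference cohort.
#'
#' @param config A `sim_config`.
#' @param n_ref Reference sample size for the expectation.
#' @param seed Seed for the reference draw.
#' @return Implied effect in exposure units per unit log-odds (multiply by
#'   `log(2)` for the per-doubling scale).
#' @export
implied_reverse_effect <- function(config, n_ref = 200000, seed = 1L) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(seed)
  G <- simulate_genotypes(n_ref, config$maf)
  U <- rnorm(n_ref)
  eps <- rnorm(n_ref, sd = config$exposure_sd)
  x <- config$exposure_mean + drop(G %*% config$gamma) +
    config$confounder_effect_x * U + eps
  eta <- config$baseline_logodds + config$causal_beta * x +
    config$confounder_effect_y * U + drop(G %*% config$pleiotropy)
  p <- plogis(eta)
  config$reverse_beta * mean(p * (1 - p))
}
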