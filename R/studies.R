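# Replicate simulation studies: run a scenario many times and collect tidy
# per-replicate estimates. These back the package's calibration checks
# (parameter recovery, type-I error, confounding contrast, pleiotropy
# sensitivity, heterogeneity calibration).

#' Replicate an MR analysis over simulated cohorts
#'
#' Runs [run_forward()] or [run_reverse()] `n_reps` times under a scenario,
#' with per-replicate seeds derived from the master seed, and returns the
#' tidy estimate rows stacked with a `rep` column. Heterogeneity (Q) and the
#' observational whole-cohort log-OR are attached per replicate when
#' requested.
#'
#' @param scenario Scenario name or [sim_config()].
#' @param n_reps Number of replicate runs.
#' @param seed Master seed.
#' @param direction `"forward"` or `"reverse"`.
#' @param estimators Two-sample roster (default IVW only, the cheapest).
#' @param arms MR arms to run.
#' @param n_boot Weighted-median bootstrap replicates.
#' @param observational Also fit the whole-cohort logistic exposure-outcome
#'   regression per replicate (adds rows with `method = "observational"`).
#' @param n_individuals,overrides Optional scenario overrides (see
#'   [mr_scenario()]).
#' @return Tibble of estimate rows with columns `rep`, `method`, `arm`,
#'   `beta`, `se`, `ci_low`, `ci_high`, `pvalue`, `n_snps`, `scale`, plus
#'   `q`/`q_df` from the two-sample heterogeneity when available.
#' @export
mr_replicate_study <- function(scenario, n_reps, seed,
                               direction = c("forward", "reverse"),
                               estimators = "ivw",
                               arms = c("one_sample", "two_sample"),
                               n_boot = 200, observational = FALSE,
                               n_individuals = NULL, overrides = list()) {
  direction <- match.arg(direction)
  if (is.character(scenario)) {
    scenario <- mr_scenario(scenario, n_individuals = n_individuals,
                            overrides = overrides)
  }
  seeds <- derive_seeds(seed, n_reps)
  runner <- if (direction == "forward") run_forward else run_reverse
  purrr::map_dfr(seq_len(n_reps), function(r) {
    cfg <- analysis_config(
      scenario, direction = direction, estimators = estimators,
      arms = arms, n_boot = n_boot, seed = seeds[r]
    )
    sec <- runner(cfg)
    est <- sec$estimates
    est$rep <- r
    if (!is.null(sec$heterogeneity)) {
      est$q <- sec$heterogeneity$q
      est$q_df <- as.integer(sec$heterogeneity$df)
    }
    if (observational) {
      obs <- run_observational(cfg)
      row <- obs$strata[obs$strata$stratum == "all", ]
      est <- dplyr::bind_rows(est, tibble::tibble(
        method = "observational", arm = "observational",
        beta = row$lnor, se = row$se, pvalue = row$pvalue, rep = r,
        scale = "per_unit", exposure_scale = "continuous"
      ))
    }
    est
  })
}

#' Monte-Carlo summary of replicated estimates
#'
#' Summarises one method's replicate rows: mean and Monte-Carlo SE of the
#' estimate, empirical rejection rate at the 5% level, and coverage of a
#' true value's 95% CI.
#'
#' @param reps Output of [mr_replicate_study()].
#' @param method Method name to summarise (e.g. `"combined"`, `"ivw_fixed"`).
#' @param truth True effect for coverage/centring checks (default 0).
#' @param arm Optional arm filter (e.g. `"combined_per_doubling"`).
#' @return One-row tibble: `n_reps`, `mean_beta`, `mc_se` (SE of the mean),
#'   `mean_se`, `reject_rate`, `coverage`.
#' @export
summarize_replicates <- function(reps, method, truth = 0, arm = NULL) {
  d <- reps[reps$method == method, , drop = FALSE]
  if (!is.null(arm)) d <- d[d$arm == arm, , drop = FALSE]
  stopifnot(nrow(d) > 0)
  tibble::tibble(
    n_reps = nrow(d),
    mean_beta = mean(d$beta),
    mc_se = sd(d$beta) / sqrt(nrow(d)),
    mean_se = mean(d$se),
    reject_rate = mean(d$pvalue < 0.05),
    coverage = mean(d$ci_low <= truth & truth <= d$ci_high)
  )
}
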