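# Orchestration: run the bidirectional analysis from one configuration —
# simulate (or accept) cohorts, build instruments, run one- and two-sample
# estimators, combine arms by fixed-effect meta-analysis, rescale reverse
# estimates to the doubling-of-odds scale, and emit a structured report.

#' Analysis configuration
#'
#' Bundles everything one full run needs. In simulation mode the two-sample
#' stage draws an independent second cohort for the outcome-trait summary
#' statistics so the two arms do not share outcome data (an
#' `overlap_fraction` knob deliberately reintroduces sample overlap to study
#' the direction of the resulting bias, which is toward the null).
#'
#' @param sim A [sim_config()] or scenario name for [mr_scenario()].
#' @param direction `"forward"`, `"reverse"` or `"both"`.
#' @param estimators Two-sample roster, subset of
#'   `c("ivw", "egger", "weighted_median")`.
#' @param ivw_mode `"fixed"` or `"multiplicative_random"`.
#' @param ivw_debiased Use the debiased IVW denominator (see [mr_ivw()]).
#'   Default `TRUE`: simulated per-SNP instruments are individually weak
#'   (F of order 10 or below), where the classical IVW denominator dilutes
#'   the estimate toward the null.
#' @param arms Which MR arms to run: subset of
#'   `c("one_sample", "two_sample")`.
#' @param n_boot Bootstrap replicates for the weighted median.
#' @param covariates Covariate column names for the one-sample models.
#' @param strata List of `c(lower, upper)` exposure intervals (half-open,
#'   kg/m^2) for the observational analysis.
#' @param overlap_fraction Fraction of the one-sample cohort reused in the
#'   outcome-GWAS cohort (0 = fully independent samples).
#' @param seed Master seed; every stochastic stage derives its own seed from
#'   it.
#' @return A list of class `mr_analysis_config`.
#' @export
analysis_config <- function(sim, direction = c("both", "forward", "reverse"),
                            estimators = c("ivw", "egger", "weighted_median"),
                            ivw_mode = "fixed", ivw_debiased = TRUE,
                            arms = c("one_sample", "two_sample"),
                            n_boot = 1000, covariates = character(0),
                            strata = list(c(25, 30), c(30, Inf)),
                            overlap_fraction = 0, seed = 1L) {
  direction <- match.arg(direction)
  if (is.character(sim)) sim <- mr_scenario(sim)
  stopifnot(inherits(sim, "sim_config"))
  stopifnot(overlap_fraction >= 0, overlap_fraction <= 1)
  structure(
    list(sim = sim, direction = direction, estimators = estimators,
         ivw_mode = ivw_mode, ivw_debiased = ivw_debiased,
         arms = arms, n_boot = n_boot,
         covariates = covariates, strata = strata,
         overlap_fraction = overlap_fraction, seed = as.integer(seed)),
    class = "mr_analysis_config"
  )
}

# simulate the one-sample cohort (A) and the independent outcome-GWAS
# cohort (B), honouring the overlap knob
simulate_cohort_pair <- function(config) {
  seeds <- derive_seeds(config$seed, 3)
  a <- simulate_cohort(config$sim, seed = seeds[1])
  b <- simulate_cohort(config$sim, seed = seeds[2])
  if (config$overlap_fraction > 0) {
    n <- config$sim$n_individuals
    n_shared <- floor(config$overlap_fraction * n)
    if (n_shared > 0) {
      idx <- seq_len(n_shared)
      b$genotypes[idx, ] <- a$genotypes[idx, ]
      b$data[idx, ] <- a$data[idx, ]
    }
  }
  list(a = a, b = b, boot_seed = seeds[3])
}

run_direction <- function(config, cohorts, direction) {
  a <- cohorts$a
  b <- cohorts$b
  forward <- direction == "forward"
  snps <- if (forward) {
    config$sim$instruments_exposure
  } else {
    config$sim$instruments_outcome
  }
  if (length(snps) == 0) {
    abort(sprintf("[%s] no instrument SNPs defined for this direction.", direction))
  }
  exposure_scale <- if (forward) "continuous" else "log_odds"
  # trait names on each side of this direction
  exp_trait <- if (forward) "exposure" else "outcome"
  out_trait <- if (forward) "outcome" else "exposure"

  stage <- function(what, expr) {
    tryCatch(expr, error = function(e) {
      abort(sprintf("[%s/%s] %s", direction, what, conditionMessage(e)))
    })
  }

  # instrument-trait GWAS in cohort A, outcome-trait GWAS in cohort B
  exp_stats <- stage("exposure_gwas",
                     cohort_to_summary_stats(a, exp_trait, snps = snps))
  out_stats <- stage("outcome_gwas",
                     cohort_to_summary_stats(b, out_trait, snps = snps))
  harm <- stage("harmonize", harmonize(exp_stats, out_stats))

  # GRS in cohort A with external weights: the instrument-trait effects
  # estimated in the independent second cohort (as when weighting by a
  # published GWAS), avoiding the overfitting of internally derived weights
  weight_stats <- stage("grs_weights",
                        cohort_to_summary_stats(b, exp_trait, snps = snps))
  G <- a$genotypes[, snps, drop = FALSE]
  ok <- !is.na(weight_stats$se)
  score <- stage("grs", build_grs(G[, ok, drop = FALSE], weight_stats$beta[ok]))
  focal <- a$data[[exp_trait]]
  diag_tbl <- stage("diagnostics", {
    d <- if (forward) {
      instrument_strength(score, focal, k = 1)
    } else {
      # binary focal trait: pseudo-R^2 not defined here; report Wald-based F
      fit <- stage_fit(focal, cbind(1, score), "binomial")
      tibble::tibble(
        f_statistic = (fit$coef[2] / sqrt(fit$vcov[2, 2]))^2,
        r_squared = NA_real_, n = length(score), k = 1
      )
    }
    d
  })
  conf <- stage("confounder_screen",
                confounder_screen(score, a$data[setdiff(names(a$data),
                                                        c("exposure", "outcome"))]))

  estimates <- list()
  if ("one_sample" %in% config$arms) {
    one <- stage("one_sample", mr_grs_ratio(
      a$data, score,
      exposure = exp_trait, outcome = out_trait,
      covariates = config$covariates,
      exposure_type = if (forward) "continuous" else "binary",
      outcome_type = if (forward) "binary" else "continuous"
    ))
    est1 <- one$estimate
    est1$arm <- "one_sample"
    estimates <- c(estimates, list(est1))
  } else {
    one <- NULL
  }
  het <- NULL
  egger_intercept <- NULL
  if ("two_sample" %in% config$arms) {
    two <- stage("two_sample", mr_all(
      harm, estimators = config$estimators, ivw_mode = config$ivw_mode,
      ivw_debiased = isTRUE(config$ivw_debiased),
      n_boot = config$n_boot, seed = cohorts$boot_seed,
      exposure_scale = exposure_scale
    ))
    het <- attr(two, "heterogeneity")
    two$arm <- "two_sample"
    egger_intercept <- dplyr::filter(two, .data$method == "egger_intercept")
    estimates <- c(estimates, list(two))
  }
  estimates <- dplyr::bind_rows(estimates)
  if ("one_sample" %in% config$arms) {
    # annotate the one-sample arm's exposure scale consistently
    estimates$exposure_scale <- exposure_scale
  }

  # combine the 1-sample ratio and the 2-sample IVW by fixed-effect pooling
  combine_rows <- dplyr::filter(
    estimates, .data$method %in% c("ratio_binary", "ivw_fixed", "ivw_mre")
  )
  combined_meta <- NULL
  if (nrow(combine_rows) >= 1) {
    combined_meta <- meta_fixed(combine_rows[, c("beta", "se")])
    comb <- mr_estimate("combined", combined_meta$pooled$beta,
                        combined_meta$pooled$se,
                        max(estimates$n_snps),
                        exposure_scale = exposure_scale)
    comb$arm <- "combined"
    estimates <- dplyr::bind_rows(estimates, comb)
  }

  if (forward) {
    estimates <- to_odds_ratio(estimates)
  } else {
    doubled <- scale_per_doubling(
      dplyr::filter(estimates, .data$method != "egger_intercept")
    )
    doubled$arm <- paste0(doubled$arm, "_per_doubling")
    estimates <- dplyr::bind_rows(estimates, doubled)
  }
  list(
    direction = direction,
    diagnostics = diag_tbl,
    confounders = conf,
    estimates = estimates,
    heterogeneity = het,
    egger_intercept = egger_intercept,
    harmonized = harm,
    one_sample = one,
    combined = combined_meta
  )
}

#' Run the forward (exposure -> outcome) MR analysis
#'
#' Simulates the cohort pair from the configuration, builds the exposure GRS,
#' runs the one-sample logistic ratio estimator and the two-sample roster on
#' harmonized summary statistics, computes heterogeneity and the Egger
#' intercept, pools the one- and two-sample arms by fixed-effect
#' meta-analysis, and reports odds ratios per exposure unit.
#'
#' @param config An [analysis_config()].
#' @return A list of class `mr_report_section`: tidy `estimates`,
#'   `diagnostics`, `confounders`, `heterogeneity`, `egger_intercept`,
#'   the `harmonized` set, the `one_sample` fit and the `combined`
#'   meta-analysis.
#' @export
run_forward <- function(config) {
  stopifnot(inherits(config, "mr_analysis_config"))
  cohorts <- simulate_cohort_pair(config)
  out <- run_direction(config, cohorts, "forward")
  structure(out, class = "mr_report_section")
}

#' Run the reverse (outcome -> exposure) MR analysis
#'
#' As [run_forward()] with the trait roles swapped: the binary trait is
#' instrumented by its own risk loci (log-odds scale), the continuous trait
#' is the outcome, and final estimates are additionally expressed per
#' doubling of the odds of the binary trait (multiplied by `ln 2`).
#'
#' @param config An [analysis_config()].
#' @return An `mr_report_section` (see [run_forward()]).
#' @export
run_reverse <- function(config) {
  stopifnot(inherits(config, "mr_analysis_config"))
  cohorts <- simulate_cohort_pair(config)
  out <- run_direction(config, cohorts, "reverse")
  structure(out, class = "mr_report_section")
}

#' Observational analysis: stratified logistic odds ratios
#'
#' Logistic regression of the binary outcome on the exposure, overall and
#' within half-open exposure strata (default overweight \[25, 30) and obese
#' \[30, Inf) kg/m^2), reporting the OR per exposure unit. Strata with fewer
#' than `min_cases` cases are skipped with a log entry. When a per-study
#' OR table is supplied, it is pooled with [meta_pool()].
#'
#' @param config An [analysis_config()].
#' @param cohort Optional `mr_cohort` (default: simulated from the
#'   configuration).
#' @param studies Optional per-study tibble (`label`, `or`, `ci_low`,
#'   `ci_high`, optional `group`) for meta-analytic pooling.
#' @param min_cases Minimum cases per stratum (default 10).
#' @param meta_model Pooling model for `studies`.
#' @return List of class `mr_observational`: `strata` tibble (one row per
#'   stratum incl. `"all"`), optional `meta` tibble, `skipped` log.
#' @export
run_observational <- function(config, cohort = NULL, studies = NULL,
                              min_cases = 10, meta_model = "random") {
  stopifnot(inherits(config, "mr_analysis_config"))
  if (is.null(cohort)) {
    cohort <- simulate_cohort(config$sim, seed = derive_seeds(config$seed, 1))
  }
  x <- cohort$data$exposure
  y <- cohort$data$outcome
  strata <- c(list(all = c(-Inf, Inf)),
              setNames(config$strata,
                       vapply(config$strata, function(s) {
                         sprintf("[%s,%s)", format(s[1]), format(s[2]))
                       }, character(1))))
  skipped <- character(0)
  rows <- purrr::imap(strata, function(bounds, label) {
    inside <- x >= bounds[1] & x < bounds[2]
    xs <- x[inside]; ys <- y[inside]
    if (sum(ys) < min_cases || sum(1 - ys) < min_cases || var(xs) == 0) {
      skipped <<- c(skipped, label)
      return(NULL)
    }
    fit <- stage_fit(ys, cbind(1, xs), "binomial")
    b <- unname(fit$coef[2]); se <- sqrt(fit$vcov[2, 2])
    z <- z95()
    tibble::tibble(
      stratum = label, n = length(ys), cases = sum(ys),
      lnor = b, se = se,
      or = exp(b), or_ci_low = exp(b - z * se), or_ci_high = exp(b + z * se),
      pvalue = two_sided_p(b, se)
    )
  })
  out <- list(strata = dplyr::bind_rows(rows), skipped = skipped)
  if (!is.null(studies)) {
    out$meta <- meta_pool(study_estimates(studies), model = meta_model)
  }
  structure(out, class = "mr_observational")
}

#' Run the full bidirectional analysis
#'
#' Executes the forward and/or reverse MR sections plus the observational
#' section and collects them with run metadata into one report.
#'
#' @param config An [analysis_config()].
#' @param studies Optional per-study OR table for the observational
#'   meta-analysis.
#' @return A list of class `mr_report` with elements `forward`, `reverse`,
#'   `observational` (as applicable) and `meta` (seed, package version,
#'   timestamp).
#' @export
run_analysis <- function(config, studies = NULL) {
  stopifnot(inherits(config, "mr_analysis_config"))
  report <- list()
  if (config$direction %in% c("forward", "both")) {
    report$forward <- run_forward(config)
  }
  if (config$direction %in% c("reverse", "both")) {
    report$reverse <- run_reverse(config)
  }
  report$observational <- run_observational(config, studies = studies)
  report$meta <- list(
    seed = config$seed,
    package_version = as.character(utils::packageVersion("grsmr")),
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    timestamp = format(Sys.time(), tz = "UTC")
  )
  structure(report, class = "mr_report")
}

#' @rdname run_analysis
#' @param x An `mr_report`.
#' @param ... Unused.
#' @export
tidy.mr_report <- function(x, ...) {
  sections <- list()
  for (dir in c("forward", "reverse")) {
    if (!is.null(x[[dir]])) {
      est <- x[[dir]]$estimates
      est$direction <- dir
      sections <- c(sections, list(est))
    }
  }
  dplyr::bind_rows(sections)
}

#' Write a report's tables to a directory
#'
#' Emits deterministic CSV tables (one per section) plus a machine-readable
#' `run_metadata.json`. Repeated runs with the same seed produce
#' byte-identical files. The timestamp is excluded from the CSVs for that
#' reason and kept only in the metadata file.
#'
#' @param report An `mr_report`.
#' @param dir Output directory (created if needed).
#' @param timestamp Include the timestamp in `run_metadata.json`.
#' @return Invisibly, the paths written.
#' @export
write_report <- function(report, dir, timestamp = TRUE) {
  stopifnot(inherits(report, "mr_report"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fmt <- function(d) dplyr::mutate(d, dplyr::across(
    dplyr::where(is.numeric), ~ signif(.x, 10)
  ))
  paths <- character(0)
  emit <- function(tbl, name) {
    p <- file.path(dir, paste0(name, ".csv"))
    readr::write_csv(fmt(tibble::as_tibble(tbl)), p, progress = FALSE)
    paths <<- c(paths, p)
  }
  for (dname in c("forward", "reverse")) {
    sec <- report[[dname]]
    if (is.null(sec)) next
    emit(sec$estimates, paste0(dname, "_estimates"))
    emit(sec$diagnostics, paste0(dname, "_diagnostics"))
    emit(sec$confounders, paste0(dname, "_confounders"))
    if (!is.null(sec$heterogeneity)) {
      emit(sec$heterogeneity, paste0(dname, "_heterogeneity"))
    }
  }
  if (!is.null(report$observational)) {
    emit(report$observational$strata, "observational_strata")
    if (!is.null(report$observational$meta)) {
      emit(report$observational$meta, "observational_meta")
    }
  }
  meta <- report$meta
  if (!timestamp) meta$timestamp <- NULL
  mpath <- file.path(dir, "run_metadata.json")
  jsonlite::write_json(meta, mpath, auto_unbox = TRUE, pretty = TRUE)
  invisible(c(paths, mpath))
}
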