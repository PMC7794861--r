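# Two-sample MR estimators on a harmonized instrument set:
# per-SNP Wald ratios, inverse-variance-weighted (IVW) pooling, MR-Egger
# regression, the weighted median, Cochran's Q, and scale transforms.
#
# Throughout, gamma denotes the SNP-exposure effect and Gamma the
# SNP-outcome effect; the causal estimate is on the outcome scale per
# exposure unit (log-odds per unit for a binary outcome).

mr_estimate <- function(method, beta, se, n_snps,
                        scale = "per_unit", exposure_scale = "continuous") {
  z <- z95()
  beta <- unname(beta)
  se <- unname(se)
  tibble::tibble(
    method = method, beta = beta, se = se,
    ci_low = beta - z * se, ci_high = beta + z * se,
    pvalue = two_sided_p(beta, se),
    n_snps = as.integer(n_snps), scale = scale,
    exposure_scale = exposure_scale
  ) |>
    structure(class = c("mr_estimate", class(tibble::tibble())))
}

check_harmonized <- function(set, min_snps = 1) {
  stopifnot(is.data.frame(set))
  need <- c("beta_exp", "se_exp", "beta_out", "se_out")
  if (!all(need %in% names(set))) {
    abort("expected a harmonized set with columns beta_exp/se_exp/beta_out/se_out.")
  }
  if (nrow(set) < min_snps) {
    abort(sprintf("need at least %d harmonized SNP(s).", min_snps))
  }
  invisible(set)
}

#' Per-SNP Wald ratio estimate
#'
#' `beta = Gamma / gamma` with first-order delta-method standard error
#' `se_Gamma / |gamma|`; the second-order option adds the
#' `Gamma^2 se_gamma^2 / gamma^4` term, acknowledging uncertainty in the
#' SNP-exposure effect.
#'
#' @param gamma,se_gamma SNP-exposure effect and its SE (`gamma` must be
#'   nonzero).
#' @param Gamma,se_Gamma SNP-outcome effect and its SE.
#' @param second_order Include exposure-side uncertainty in the SE.
#' @param exposure_scale `"continuous"` or `"log_odds"` (binary exposure,
#'   reverse direction); recorded in the estimate.
#' @return One-row `mr_estimate` tibble.
#' @export
wald_ratio <- function(gamma, se_gamma, Gamma, se_Gamma,
                       second_order = FALSE, exposure_scale = "continuous") {
  if (gamma == 0) abort("weak/null instrument for ratio: gamma = 0.")
  beta <- Gamma / gamma
  se <- if (second_order) {
    sqrt(se_Gamma^2 / gamma^2 + Gamma^2 * se_gamma^2 / gamma^4)
  } else {
    se_Gamma / abs(gamma)
  }
  mr_estimate("wald", beta, se, 1L, exposure_scale = exposure_scale)
}

ivw_weights <- function(set) 1 / set$se_out^2

ivw_point <- function(set) {
  w <- ivw_weights(set)
  sum(w * set$beta_exp * set$beta_out) / sum(w * set$beta_exp^2)
}

#' Inverse-variance-weighted (IVW) estimator
#'
#' Precision-weighted combination of per-SNP Wald ratios,
#' `beta = sum(w g G) / sum(w g^2)` with `w = 1/se_Gamma^2`; equivalent to
#' weighted least squares of the outcome effects on the exposure effects
#' through the origin. Fixed-effect SE is `sqrt(1 / sum(w g^2))`; the
#' multiplicative random-effects mode inflates it by
#' `sqrt(max(1, Q / (J - 1)))`.
#'
#' @details With many individually weak instruments the plain IVW estimator
#' is diluted toward the null by the sampling error of the SNP-exposure
#' effects (by a factor of roughly `F / (F + 1)` at mean per-SNP F-statistic
#' `F`): the denominator `sum(w g_hat^2)` overestimates `sum(w g^2)` by
#' `sum(w se_gamma^2)`. `debiased = TRUE` subtracts that term (the debiased
#' IVW of the many-weak-instrument literature), with a delta-method SE that
#' accounts for the exposure-side noise; it reduces to the plain estimator
#' as the exposure-side SEs shrink to zero.
#'
#' @param set An `mr_harmonized` set with at least one SNP with nonzero
#'   exposure effect.
#' @param mode `"fixed"` or `"multiplicative_random"`.
#' @param debiased Subtract the exposure-side sampling variance from the
#'   denominator (see Details). Default `FALSE` (the classical estimator).
#' @param exposure_scale Scale annotation propagated to the estimate.
#' @return One-row `mr_estimate` (method `ivw_fixed` or `ivw_mre`).
#' @export
mr_ivw <- function(set, mode = c("fixed", "multiplicative_random"),
                   debiased = FALSE, exposure_scale = "continuous") {
  mode <- match.arg(mode)
  check_harmonized(set, 1)
  set <- set[set$beta_exp != 0, , drop = FALSE]
  if (nrow(set) == 0) abort("no SNP with nonzero exposure effect.")
  J <- nrow(set)
  w <- ivw_weights(set)
  g <- set$beta_exp
  if (debiased) {
    den <- sum(w * (g^2 - set$se_exp^2))
    if (den <= 0) {
      warn("debiased IVW denominator is non-positive (instruments too weak); falling back to the classical denominator.")
      den <- sum(w * g^2)
    }
    beta <- sum(w * g * set$beta_out) / den
    # delta-method variance; E[g_hat^2] = g^2 + se_gamma^2 already carries
    # the exposure-side noise term, so g_hat^2 multiplies the error variance
    v <- sum(w^2 * (g^2 * (set$se_out^2 + beta^2 * set$se_exp^2) +
                      beta^2 * set$se_exp^4))
    se <- sqrt(v) / den
  } else {
    beta <- ivw_point(set)
    se <- sqrt(1 / sum(w * g^2))
  }
  method <- "ivw_fixed"
  if (mode == "multiplicative_random") {
    if (J == 1) {
      inform("single SNP: multiplicative random-effects IVW falls back to fixed.")
    } else {
      q <- sum(w * (set$beta_out - beta * g)^2)
      se <- se * sqrt(max(1, q / (J - 1)))
      method <- "ivw_mre"
    }
  }
  mr_estimate(method, beta, se, J, exposure_scale = exposure_scale)
}

#' MR-Egger regression
#'
#' Weighted linear regression of outcome effects on exposure effects with an
#' unconstrained intercept (weights `1/se_Gamma^2`), after orienting all
#' exposure effects positive (flipping the paired outcome effect with them).
#' The slope estimates the causal effect under the InSIDE assumption; the
#' intercept estimates average directional pleiotropy. Standard errors use a
#' multiplicative residual inflation factor `max(1, RSS / (J - 2))`.
#'
#' @param set An `mr_harmonized` set with at least 3 SNPs.
#' @param exposure_scale Scale annotation propagated to the estimates.
#' @return Two-row `mr_estimate` tibble (methods `egger_slope`,
#'   `egger_intercept`).
#' @export
mr_egger <- function(set, exposure_scale = "continuous") {
  check_harmonized(set, 3)
  J <- nrow(set)
  if (J < 3) abort("insufficient instruments for Egger (need >= 3).")
  flip <- sign(set$beta_exp)
  flip[flip == 0] <- 1
  g <- set$beta_exp * flip
  G <- set$beta_out * flip
  w <- 1 / set$se_out^2
  # weighted normal equations with intercept
  sw <- sum(w); swg <- sum(w * g); swg2 <- sum(w * g^2)
  swG <- sum(w * G); swgG <- sum(w * g * G)
  det <- sw * swg2 - swg^2
  if (det <= 0) abort("degenerate design for Egger regression.")
  slope <- (sw * swgG - swg * swG) / det
  intercept <- (swg2 * swG - swg * swgG) / det
  rss <- sum(w * (G - intercept - slope * g)^2)
  infl <- max(1, rss / (J - 2))
  se_slope <- sqrt(infl * sw / det)
  se_int <- sqrt(infl * swg2 / det)
  dplyr::bind_rows(
    mr_estimate("egger_slope", slope, se_slope, J,
                exposure_scale = exposure_scale),
    mr_estimate("egger_intercept", intercept, se_int, J,
                exposure_scale = exposure_scale)
  )
}

# interpolated weighted median of x with weights w (normalized);
# cumulative-weight midpoints, linear interpolation at 0.5
weighted_median_point <- function(x, w) {
  ord <- order(x)
  x <- x[ord]
  w <- w[ord] / sum(w)
  p <- cumsum(w) - w / 2
  if (0.5 <= p[1]) return(x[1])
  if (0.5 >= p[length(p)]) return(x[length(x)])
  stats::approx(p, x, xout = 0.5, ties = "ordered")$y
}

#' Weighted median estimator
#'
#' Median of the per-SNP Wald ratios under inverse-variance weights
#' (`1/se_ratio^2`, first-order), interpolated at cumulative weight 0.5.
#' Consistent when at least half the weight comes from valid instruments.
#' The SE comes from a parametric bootstrap: exposure and outcome effects are
#' resampled from normal distributions centred on their estimates.
#'
#' @param set An `mr_harmonized` set with at least 3 SNPs.
#' @param n_boot Bootstrap replicates (>= 2; < 100 triggers a warning).
#' @param seed Optional seed for the bootstrap.
#' @param exposure_scale Scale annotation propagated to the estimate.
#' @return One-row `mr_estimate` (method `weighted_median`).
#' @export
mr_weighted_median <- function(set, n_boot = 1000, seed = NULL,
                               exposure_scale = "continuous") {
  check_harmonized(set, 3)
  if (n_boot < 2) abort("`n_boot` must be at least 2.")
  if (n_boot < 100) warn("`n_boot` < 100 gives an unreliable bootstrap SE.")
  set <- set[set$beta_exp != 0, , drop = FALSE]
  J <- nrow(set)
  ratio <- set$beta_out / set$beta_exp
  se_ratio <- set$se_out / abs(set$beta_exp)
  w <- 1 / se_ratio^2
  est <- weighted_median_point(ratio, w)
  if (!is.null(seed)) set.seed(seed)
  bg <- matrix(rnorm(J * n_boot, set$beta_exp, set$se_exp), nrow = J)
  bG <- matrix(rnorm(J * n_boot, set$beta_out, set$se_out), nrow = J)
  boots <- vapply(seq_len(n_boot), function(b) {
    g <- bg[, b]
    g[g == 0] <- .Machine$double.eps
    r <- bG[, b] / g
    weighted_median_point(r, 1 / (set$se_out / abs(g))^2)
  }, numeric(1))
  mr_estimate("weighted_median", est, sd(boots), J,
              exposure_scale = exposure_scale)
}

#' Cochran's Q heterogeneity statistic
#'
#' `Q = sum_j w_j (beta_j - beta_pooled)^2` over the per-SNP Wald ratios with
#' first-order inverse-variance weights; `df = J - 1`; p from the upper tail
#' of chi-square(df).
#'
#' @param set An `mr_harmonized` set with at least 2 SNPs with nonzero
#'   exposure effect.
#' @param pooled Optional pooled `mr_estimate` (defaults to fixed-effect IVW
#'   of `set`).
#' @return One-row tibble: `q`, `df`, `pvalue`.
#' @export
mr_cochran_q <- function(set, pooled = NULL) {
  check_harmonized(set, 2)
  set <- set[set$beta_exp != 0, , drop = FALSE]
  J <- nrow(set)
  if (J < 2) abort("need at least 2 SNPs with nonzero exposure effect.")
  b0 <- if (is.null(pooled)) ivw_point(set) else pooled$beta[1]
  ratio <- set$beta_out / set$beta_exp
  w <- set$beta_exp^2 / set$se_out^2  # 1 / se_ratio^2
  q <- sum(w * (ratio - b0)^2)
  tibble::tibble(q = q, df = J - 1L, pvalue = pchisq(q, J - 1, lower.tail = FALSE))
}

#' Rescale a binary-exposure estimate to the per-doubling-of-odds scale
#'
#' For reverse-direction MR with a binary exposure, effects are naturally in
#' outcome units per unit log-odds of the exposure; multiplying by `ln 2`
#' expresses them per doubling of the exposure odds.
#'
#' @param est An `mr_estimate` with `scale == "per_unit"` and
#'   `exposure_scale == "log_odds"`.
#' @return The estimate with beta, SE and CI multiplied by `log(2)` and
#'   `scale = "per_doubling"`.
#' @export
scale_per_doubling <- function(est) {
  stopifnot(is.data.frame(est))
  if (any(est$scale != "per_unit")) {
    abort("estimate is not on the per_unit scale.")
  }
  if (any(est$exposure_scale != "log_odds")) {
    abort("per-doubling scaling applies only to a log-odds (binary) exposure.")
  }
  est$beta <- est$beta * log(2)
  est$se <- est$se * log(2)
  est$ci_low <- est$ci_low * log(2)
  est$ci_high <- est$ci_high * log(2)
  est$scale <- "per_doubling"
  est
}

#' Express a log-odds estimate as an odds ratio
#'
#' Exponentiates a log-odds-scale causal estimate and its CI for reporting;
#' the original log-scale columns are retained alongside.
#'
#' @param est An `mr_estimate` tibble (one or more rows) on the log-odds
#'   outcome scale.
#' @return The input with added columns `or`, `or_ci_low`, `or_ci_high` and
#'   `scale = "odds_ratio"` annotation columns.
#' @export
to_odds_ratio <- function(est) {
  stopifnot(is.data.frame(est))
  est$or <- exp(est$beta)
  est$or_ci_low <- exp(est$ci_low)
  est$or_ci_high <- exp(est$ci_high)
  est
}

#' Run a roster of two-sample MR estimators
#'
#' Convenience wrapper applying any of IVW, MR-Egger and the weighted median
#' to one harmonized set and row-binding the tidy estimates, with Cochran's Q
#' attached as an attribute.
#'
#' @param set An `mr_harmonized` set.
#' @param estimators Subset of `c("ivw", "egger", "weighted_median")`.
#' @param ivw_mode,ivw_debiased Passed to [mr_ivw()].
#' @param n_boot,seed Passed to [mr_weighted_median()].
#' @param exposure_scale Scale annotation.
#' @return `mr_estimate` tibble, one row per method (two for Egger), with
#'   attribute `heterogeneity` (the [mr_cochran_q()] row when J >= 2).
#' @export
mr_all <- function(set, estimators = c("ivw", "egger", "weighted_median"),
                   ivw_mode = "fixed", ivw_debiased = FALSE,
                   n_boot = 1000, seed = NULL,
                   exposure_scale = "continuous") {
  rows <- list()
  if ("ivw" %in% estimators) {
    rows <- c(rows, list(mr_ivw(set, ivw_mode, debiased = ivw_debiased,
                                exposure_scale = exposure_scale)))
  }
  if ("egger" %in% estimators && nrow(set) >= 3) {
    rows <- c(rows, list(mr_egger(set, exposure_scale = exposure_scale)))
  }
  if ("weighted_median" %in% estimators && nrow(set) >= 3) {
    rows <- c(rows, list(mr_weighted_median(set, n_boot = n_boot, seed = seed,
                                            exposure_scale = exposure_scale)))
  }
  out <- dplyr::bind_rows(rows)
  if (sum(set$beta_exp != 0) >= 2) {
    attr(out, "heterogeneity") <- mr_cochran_q(set)
  }
  out
}
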