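# Meta-analytic pooling: fixed-effect inverse-variance combination (used to
# merge one- and two-sample MR arms) and DerSimonian-Laird random effects
# (used for observational odds-ratio syntheses), with Q, I^2 and tau^2.

#' Convert odds ratios with confidence intervals to log-scale estimates
#'
#' `beta = ln(OR)`, `se = (ln(ci_high) - ln(ci_low)) / (2 * 1.96)` — the
#' standard CI-width reconstruction for published per-study odds ratios.
#'
#' @param data Tibble with columns `label`, `or`, `ci_low`, `ci_high` and
#'   optionally `group`.
#' @return Tibble with `label`, `beta`, `se` (plus `group` if present).
#' @export
study_estimates <- function(data) {
  data <- tibble::as_tibble(data)
  need <- c("label", "or", "ci_low", "ci_high")
  missing <- setdiff(need, names(data))
  if (length(missing)) {
    abort(paste0("missing column(s): ", paste(missing, collapse = ", ")))
  }
  if (any(data$ci_low <= 0 | data$ci_high <= data$ci_low)) {
    abort("confidence limits must satisfy 0 < ci_low < ci_high.")
  }
  out <- tibble::tibble(
    label = data$label,
    beta = log(data$or),
    se = (log(data$ci_high) - log(data$ci_low)) / (2 * z95())
  )
  if ("group" %in% names(data)) out$group <- data$group
  out
}

new_meta_result <- function(beta, se, k, q, df, tau2, model, labels) {
  z <- z95()
  structure(
    list(
      pooled = tibble::tibble(
        beta = beta, se = se, ci_low = beta - z * se, ci_high = beta + z * se,
        pvalue = two_sided_p(beta, se)
      ),
      k = k, q = q, df = df,
      i_squared = if (df > 0 && q > 0) max(0, (q - df) / q) else 0,
      tau_squared = tau2, model = model, labels = labels
    ),
    class = "mr_meta"
  )
}

meta_check <- function(estimates, min_k) {
  estimates <- tibble::as_tibble(estimates)
  if (!all(c("beta", "se") %in% names(estimates))) {
    abort("`estimates` needs columns `beta` and `se`.")
  }
  if (nrow(estimates) < min_k) {
    abort(sprintf("need at least %d estimate(s).", min_k))
  }
  if (any(!is.finite(estimates$se) | estimates$se <= 0)) {
    abort("all standard errors must be finite and positive.")
  }
  estimates
}

#' Fixed-effect inverse-variance meta-analysis
#'
#' `beta = sum(b_i / se_i^2) / sum(1 / se_i^2)`,
#' `se = sqrt(1 / sum(1 / se_i^2))`; Cochran's Q with `df = k - 1`.
#'
#' @param estimates Tibble with columns `beta`, `se` and optionally `label`.
#' @return An `mr_meta` object (`model = "fixed"`, `tau_squared = 0`).
#' @export
meta_fixed <- function(estimates) {
  e <- meta_check(estimates, 1)
  w <- 1 / e$se^2
  beta <- sum(w * e$beta) / sum(w)
  se <- sqrt(1 / sum(w))
  q <- sum(w * (e$beta - beta)^2)
  new_meta_result(beta, se, nrow(e), q, nrow(e) - 1L, 0, "fixed",
                  if ("label" %in% names(e)) e$label else NULL)
}

#' DerSimonian-Laird random-effects meta-analysis
#'
#' Moment estimator of between-study variance,
#' `tau^2 = max(0, (Q - df) / (sum(w) - sum(w^2)/sum(w)))` with fixed-effect
#' weights `w = 1/se^2`, then re-pooling with weights `1/(se^2 + tau^2)`.
#' When `Q <= df` the result coincides with [meta_fixed()].
#'
#' @param estimates Tibble with columns `beta`, `se` (k >= 2) and optionally
#'   `label`.
#' @return An `mr_meta` object (`model = "random"`).
#' @export
meta_dl <- function(estimates) {
  e <- meta_check(estimates, 2)
  w <- 1 / e$se^2
  bf <- sum(w * e$beta) / sum(w)
  q <- sum(w * (e$beta - bf)^2)
  df <- nrow(e) - 1L
  denom <- sum(w) - sum(w^2) / sum(w)
  tau2 <- max(0, (q - df) / denom)
  wr <- 1 / (e$se^2 + tau2)
  beta <- sum(wr * e$beta) / sum(wr)
  se <- sqrt(1 / sum(wr))
  new_meta_result(beta, se, nrow(e), q, df, tau2, "random",
                  if ("label" %in% names(e)) e$label else NULL)
}

#' Pool study estimates, optionally within groups
#'
#' Applies [meta_fixed()] or [meta_dl()] per level of a grouping column
#' (e.g. adult/child x overweight/obese strata) and returns one tidy row per
#' group.
#'
#' @param estimates Tibble with `beta`, `se` and optionally `group`.
#' @param model `"fixed"` or `"random"`.
#' @return Tibble of pooled rows (see [or_table_report()] columns).
#' @export
meta_pool <- function(estimates, model = c("random", "fixed")) {
  model <- match.arg(model)
  estimates <- tibble::as_tibble(estimates)
  pool1 <- function(d, label) {
    fit <- if (model == "fixed" || nrow(d) < 2) meta_fixed(d) else meta_dl(d)
    dplyr::mutate(or_table_report(fit), group = label, .before = 1)
  }
  if (!"group" %in% names(estimates)) {
    return(pool1(estimates, "all"))
  }
  groups <- split(estimates, estimates$group)
  dplyr::bind_rows(purrr::imap(groups, pool1))
}

#' Tidy odds-ratio report of a pooled result
#'
#' @param result An `mr_meta` object with a log-scale pooled estimate.
#' @return One-row tibble: `or`, `or_ci_low`, `or_ci_high`, `beta`, `se`,
#'   `pvalue`, `k`, `q`, `i_squared`, `tau_squared`, `model`.
#' @export
or_table_report <- function(result) {
  stopifnot(inherits(result, "mr_meta"))
  p <- result$pooled
  tibble::tibble(
    or = exp(p$beta), or_ci_low = exp(p$ci_low), or_ci_high = exp(p$ci_high),
    beta = p$beta, se = p$se, pvalue = p$pvalue,
    k = result$k, q = result$q, i_squared = result$i_squared,
    tau_squared = result$tau_squared, model = result$model
  )
}

#' @export
print.mr_meta <- function(x, ...) {
  p <- x$pooled
  cat(sprintf(
    "%s-effect meta-analysis of %d estimates\n  beta = %.4g [%.4g, %.4g], p = %.3g\n  Q = %.3f (df = %d), I^2 = %.1f%%, tau^2 = %.4g\n",
    x$model, x$k, p$beta, p$ci_low, p$ci_high, p$pvalue,
    x$q, x$df, 100 * x$i_squared, x$tau_squared
  ))
  invisible(x)
}

#' @rdname meta_fixed
#' @param x An `mr_meta` object.
#' @param ... Unused.
#' @export
tidy.mr_meta <- function(x, ...) {
  dplyr::mutate(x$pooled, model = x$model, .before = 1)
}

#' @rdname meta_fixed
#' @export
glance.mr_meta <- function(x, ...) {
  tibble::tibble(
    model = x$model, k = x$k, q = x$q, df = x$df,
    i_squared = x$i_squared, tau_squared = x$tau_squared
  )
}
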