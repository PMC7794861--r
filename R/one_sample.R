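# One-sample MR on individual-level data with a genetic risk score as the
# single instrument: two-stage least squares for continuous outcomes and a
# ratio-of-coefficients estimator with a logistic stage for binary traits.

new_one_sample_fit <- function(method, first_stage, reduced_form, estimate,
                               n, covariates) {
  structure(
    list(method = method, first_stage = first_stage,
         reduced_form = reduced_form, estimate = estimate,
         n = n, covariates = covariates),
    class = "one_sample_mr"
  )
}

model_frame <- function(data, vars) {
  data <- tibble::as_tibble(data)
  missing <- setdiff(vars, names(data))
  if (length(missing)) {
    abort(paste0("column(s) not found: ", paste(missing, collapse = ", ")))
  }
  data[vars]
}

stage_fit <- function(y, X, family) {
  if (identical(family, "gaussian")) {
    fit <- stats::lm.fit(X, y)
    res <- y - X %*% fit$coefficients
    df <- length(y) - ncol(X)
    sigma2 <- sum(res^2) / df
    V <- sigma2 * chol2inv(chol(crossprod(X)))
    list(coef = fit$coefficients, vcov = V, r_squared = 1 - sum(res^2) / sum((y - mean(y))^2))
  } else {
    fit <- glm.fit(X, y, family = binomial())
    V <- chol2inv(chol(crossprod(X * sqrt(fit$weights))))
    list(coef = fit$coefficients, vcov = V, r_squared = NA_real_)
  }
}

#' Two-stage least squares with a genetic risk score instrument
#'
#' Continuous-outcome one-sample MR. Stage one regresses the exposure on the
#' score (plus covariates); the causal coefficient is the just-identified IV
#' estimate with standard errors computed from the structural residuals
#' (outcome minus observed exposure times the IV coefficient), not the naive
#' second-stage residuals.
#'
#' @param data Data frame with the exposure, outcome and covariate columns.
#' @param score Instrument score vector (same length as `nrow(data)`).
#' @param exposure,outcome Column names in `data`.
#' @param covariates Character vector of covariate column names (optional).
#' @param weak_f Warn when the first-stage F falls below this (default 10).
#' @return A `one_sample_mr` object; its `$estimate` is an `mr_estimate` row
#'   with method `"tsls"`.
#' @export
mr_tsls <- function(data, score, exposure = "exposure", outcome = "outcome",
                    covariates = character(0), weak_f = 10) {
  df <- model_frame(data, c(exposure, outcome, covariates))
  n <- nrow(df)
  stopifnot(length(score) == n)
  if (var(score) <= .Machine$double.eps) abort("degenerate instrument: zero-variance score.")
  C <- if (length(covariates)) as.matrix(df[covariates]) else NULL
  x <- df[[exposure]]
  y <- df[[outcome]]
  Z <- cbind(1, score, C)
  X <- cbind(1, x, C)
  colnames(Z) <- colnames(X) <- c("(Intercept)", "focal", covariates)
  # just-identified IV: beta = (Z'X)^{-1} Z'y
  ZtX <- crossprod(Z, X)
  beta_iv <- solve(ZtX, crossprod(Z, y))
  res <- y - X %*% beta_iv
  sigma2 <- sum(res^2) / (n - ncol(X))
  bread <- solve(ZtX)
  V <- sigma2 * bread %*% crossprod(Z) %*% t(bread)
  first <- stage_fit(x, Z, "gaussian")
  first$coef <- unname(first$coef)
  fdiag <- instrument_strength(score, x, k = 1)
  if (fdiag$f_statistic < weak_f) {
    warn(sprintf("weak instrument: first-stage F = %.2f < %s.",
                 fdiag$f_statistic, format(weak_f)))
  }
  est <- mr_estimate("tsls", beta_iv[2], sqrt(V[2, 2]), 1L)
  new_one_sample_fit(
    "tsls",
    first_stage = list(coef = first$coef[2], se = sqrt(first$vcov[2, 2]),
                       r_squared = fdiag$r_squared, f = fdiag$f_statistic),
    reduced_form = list(coef = first$coef[2] * beta_iv[2], se = NA_real_,
                        family = "gaussian"),
    estimate = est, n = n, covariates = covariates
  )
}

#' Ratio-of-coefficients one-sample MR with a logistic stage
#'
#' For a binary trait on either side of the design. The first stage regresses
#' the focal exposure on the score (linear for a continuous exposure,
#' logistic for binary); the reduced form regresses the outcome on the score
#' (logistic for the binary outcome direction, linear for the reverse
#' direction). The causal estimate is the ratio of reduced-form to
#' first-stage coefficients with a first-order delta-method SE assuming the
#' stages are independent.
#'
#' @param data Data frame with exposure, outcome and covariates.
#' @param score Instrument score vector.
#' @param exposure,outcome Column names.
#' @param covariates Character vector of covariate names.
#' @param exposure_type,outcome_type `"continuous"` or `"binary"`.
#' @param weak_f Weak-instrument warning threshold for a continuous first
#'   stage.
#' @param min_cases Minimum cases required for any binary stage (default 10).
#' @return A `one_sample_mr` object; `$estimate` has method `"ratio_binary"`
#'   on the log-odds outcome scale (forward) or in outcome units per unit
#'   log-odds of the exposure (reverse), with `exposure_scale` annotated.
#' @export
mr_grs_ratio <- function(data, score, exposure = "exposure",
                         outcome = "outcome", covariates = character(0),
                         exposure_type = c("continuous", "binary"),
                         outcome_type = c("binary", "continuous"),
                         weak_f = 10, min_cases = 10) {
  exposure_type <- match.arg(exposure_type)
  outcome_type <- match.arg(outcome_type)
  df <- model_frame(data, c(exposure, outcome, covariates))
  n <- nrow(df)
  stopifnot(length(score) == n)
  if (var(score) <= .Machine$double.eps) abort("degenerate instrument: zero-variance score.")
  check_binary <- function(v, what) {
    if (!all(v %in% c(0, 1))) abort(paste0(what, " must be coded 0/1."))
    if (min(sum(v), sum(1 - v)) < min_cases) {
      abort(sprintf("insufficient cases: %s has < %d in the smaller class.",
                    what, min_cases))
    }
  }
  C <- if (length(covariates)) as.matrix(df[covariates]) else NULL
  Z <- cbind(1, score, C)
  xv <- df[[exposure]]
  yv <- df[[outcome]]
  if (exposure_type == "binary") check_binary(xv, "exposure")
  if (outcome_type == "binary") check_binary(yv, "outcome")
  first <- stage_fit(xv, Z, if (exposure_type == "binary") "binomial" else "gaussian")
  reduced <- stage_fit(yv, Z, if (outcome_type == "binary") "binomial" else "gaussian")
  g <- unname(first$coef[2]); se_g <- sqrt(first$vcov[2, 2])
  Gm <- unname(reduced$coef[2]); se_G <- sqrt(reduced$vcov[2, 2])
  if (g == 0) abort("weak/null instrument: first-stage coefficient is zero.")
  if (exposure_type == "continuous") {
    fdiag <- instrument_strength(score, xv, k = 1)
    if (fdiag$f_statistic < weak_f) {
      warn(sprintf("weak instrument: first-stage F = %.2f < %s.",
                   fdiag$f_statistic, format(weak_f)))
    }
    fs_r2 <- fdiag$r_squared; fs_f <- fdiag$f_statistic
  } else {
    fs_r2 <- NA_real_; fs_f <- (g / se_g)^2
  }
  beta <- Gm / g
  se <- sqrt(se_G^2 / g^2 + Gm^2 * se_g^2 / g^4)
  est <- mr_estimate(
    "ratio_binary", beta, se, 1L,
    exposure_scale = if (exposure_type == "binary") "log_odds" else "continuous"
  )
  new_one_sample_fit(
    "ratio_binary",
    first_stage = list(coef = g, se = se_g, r_squared = fs_r2, f = fs_f),
    reduced_form = list(coef = Gm, se = se_G,
                        family = if (outcome_type == "binary") "binomial" else "gaussian"),
    estimate = est, n = n, covariates = covariates
  )
}

#' @export
print.one_sample_mr <- function(x, ...) {
  cat("One-sample MR (", x$method, "), n = ", x$n, "\n", sep = "")
  cat(sprintf("  first stage: coef = %.4g (SE %.3g), F = %.1f\n",
              x$first_stage$coef, x$first_stage$se, x$first_stage$f))
  cat(sprintf("  causal: beta = %.4g (SE %.3g), p = %.3g\n",
              x$estimate$beta, x$estimate$se, x$estimate$pvalue))
  invisible(x)
}

#' @rdname mr_tsls
#' @param x A `one_sample_mr` object.
#' @param ... Unused.
#' @export
tidy.one_sample_mr <- function(x, ...) {
  dplyr::bind_rows(
    tibble::tibble(term = "first_stage", estimate = unname(x$first_stage$coef),
                   std.error = unname(x$first_stage$se)),
    tibble::tibble(term = "reduced_form", estimate = unname(x$reduced_form$coef),
                   std.error = unname(x$reduced_form$se)),
    tibble::tibble(term = "causal", estimate = x$estimate$beta,
                   std.error = x$estimate$se)
  )
}

#' @rdname mr_tsls
#' @export
glance.one_sample_mr <- function(x, ...) {
  tibble::tibble(
    method = x$method, n = x$n,
    first_stage_f = unname(x$first_stage$f),
    first_stage_r_squared = unname(x$first_stage$r_squared),
    beta = x$estimate$beta, se = x$estimate$se, pvalue = x$estimate$pvalue
  )
}
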