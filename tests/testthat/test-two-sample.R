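# Two-sample estimators: Wald ratio, IVW, MR-Egger, weighted median,
# Cochran's Q, scale transforms.

test_that("Wald ratio matches the delta-method formulas", {
  w <- wald_ratio(0.1, 0.01, 0.002, 0.001)
  expect_equal(w$beta, 0.02)
  expect_equal(w$se, 0.01)
  expect_equal(wald_ratio(0.1, 0.01, 0, 0.001)$beta, 0)
  expect_error(wald_ratio(0, 0.01, 0.1, 0.001), "gamma")

  # second-order SE dominates first-order and tracks the sampling SD of the
  # ratio (parametric simulation oracle)
  set.seed(14)
  for (i in 1:5) {
    g <- runif(1, 0.2, 1); sg <- runif(1, 0.01, 0.05)
    G <- runif(1, -0.2, 0.2); sG <- runif(1, 0.01, 0.05)
    w1 <- wald_ratio(g, sg, G, sG)
    w2 <- wald_ratio(g, sg, G, sG, second_order = TRUE)
    expect_gte(w2$se, w1$se)
    draws <- rnorm(1e5, G, sG) / rnorm(1e5, g, sg)
    expect_lt(abs(w2$se - sd(draws)) / sd(draws), 0.1)
  }
})

test_that("IVW equals the WLS-through-origin oracle and its reductions", {
  h <- random_harmonized(10, slope = 0.05, noise = 0.01)
  est <- mr_ivw(h)
  oracle <- lm(beta_out ~ 0 + beta_exp, data = h, weights = 1 / h$se_out^2)
  expect_equal(est$beta, unname(coef(oracle)[1]), tolerance = 1e-10)

  # single SNP reduces to the Wald ratio
  h1 <- h[1, ]
  expect_equal(mr_ivw(h1)$beta,
               wald_ratio(h1$beta_exp, h1$se_exp, h1$beta_out, h1$se_out)$beta)
  expect_equal(mr_ivw(h1)$se,
               wald_ratio(h1$beta_exp, h1$se_exp, h1$beta_out, h1$se_out)$se)

  # J identical SNPs: beta is the common ratio, fixed se scales as 1/sqrt(J)
  hJ <- make_harmonized(rep(0.1, 4), rep(0.01, 4), rep(0.005, 4), rep(0.02, 4))
  estJ <- mr_ivw(hJ)
  expect_equal(estJ$beta, 0.05)
  expect_equal(estJ$se, (0.02 / 0.1) / sqrt(4))

  # multiplicative random-effects never shrinks the SE
  noisy <- random_harmonized(15, slope = 0.05, noise = 0.05, seed = 3)
  expect_gte(mr_ivw(noisy, "multiplicative_random")$se, mr_ivw(noisy)$se)
})

test_that("IVW is invariant to allele relabelling after harmonization", {
  exp <- make_sumstats(6, beta = 0.1)
  set.seed(5)
  out <- make_sumstats(6, beta = 0.005)
  out$beta <- out$beta + rnorm(6, sd = 0.002)
  base <- mr_ivw(harmonize(exp, out))
  # relabel one SNP's alleles in the outcome table (swap + sign change)
  flipped <- out
  flipped$effect_allele[3] <- "G"; flipped$other_allele[3] <- "A"
  flipped$beta[3] <- -flipped$beta[3]
  flipped$eaf[3] <- 1 - flipped$eaf[3]
  again <- mr_ivw(harmonize(exp, flipped))
  expect_equal(again$beta, base$beta, tolerance = 1e-12)
  expect_equal(again$se, base$se, tolerance = 1e-12)
})

test_that("MR-Egger matches a weighted lm oracle and needs 3 SNPs", {
  h <- random_harmonized(12, slope = 0.04, noise = 0.03, seed = 7)
  eg <- mr_egger(h)
  fit <- lm(beta_out ~ beta_exp, data = h, weights = 1 / h$se_out^2)
  expect_equal(eg$beta[eg$method == "egger_slope"],
               unname(coef(fit)[2]), tolerance = 1e-10)
  expect_equal(eg$beta[eg$method == "egger_intercept"],
               unname(coef(fit)[1]), tolerance = 1e-10)
  # with residual dispersion > 1 the inflated SEs equal lm's dispersion-based
  # SEs (multiplicative model)
  disp <- sum(1 / h$se_out^2 * residuals(fit)^2) / (12 - 2)
  if (disp > 1) {
    expect_equal(eg$se[eg$method == "egger_slope"],
                 summary(fit)$coefficients[2, 2], tolerance = 1e-8)
  }
  expect_error(mr_egger(h[1:2, ]), "3")
  # orientation: flipping a gamma sign (with its Gamma) leaves Egger unchanged
  h2 <- h
  h2$beta_exp[1] <- -h2$beta_exp[1]
  h2$beta_out[1] <- -h2$beta_out[1]
  eg2 <- mr_egger(h2)
  expect_equal(eg2$beta, eg$beta, tolerance = 1e-12)
})

test_that("weighted median reduces to known cases and matches a brute-force oracle", {
  # all ratios equal c -> estimate c
  h <- make_harmonized(rep(0.1, 5), rep(0.01, 5), rep(0.003, 5),
                       c(0.01, 0.02, 0.03, 0.02, 0.015))
  expect_equal(suppressWarnings(mr_weighted_median(h, n_boot = 100, seed = 1))$beta, 0.03)

  # equal weights, odd J -> ordinary median of the ratios
  gam <- rep(0.1, 5)
  Gam <- c(0.001, 0.005, 0.003, 0.009, 0.002)
  he <- make_harmonized(gam, rep(0.01, 5), Gam, rep(0.02, 5))
  expect_equal(mr_weighted_median(he, n_boot = 100, seed = 1)$beta,
               median(Gam / gam))

  # brute-force interpolation oracle on random sets
  for (s in 1:5) {
    hr <- random_harmonized(9, slope = 0.05, noise = 0.04, seed = s)
    ratio <- hr$beta_out / hr$beta_exp
    wgt <- (hr$beta_exp / hr$se_out)^2
    ord <- order(ratio)
    r <- ratio[ord]; wn <- wgt[ord] / sum(wgt)
    csum <- cumsum(wn) - wn / 2
    k <- max(which(csum < 0.5))
    oracle <- r[k] + (r[k + 1] - r[k]) * (0.5 - csum[k]) / (csum[k + 1] - csum[k])
    expect_equal(mr_weighted_median(hr, n_boot = 100, seed = 1)$beta, oracle)
  }
  expect_error(mr_weighted_median(he, n_boot = 1), "n_boot")
  expect_warning(mr_weighted_median(he, n_boot = 50, seed = 1), "n_boot")
})

test_that("Cochran's Q matches hand arithmetic and degenerate cases", {
  # identical ratios: Q = 0, p = 1
  hJ <- make_harmonized(rep(0.1, 4), rep(0.01, 4), rep(0.005, 4), rep(0.02, 4))
  q0 <- mr_cochran_q(hJ)
  expect_equal(q0$q, 0)
  expect_equal(q0$pvalue, 1)

  # 3-SNP hand-computed oracle from the definition
  gam <- c(0.1, 0.2, 0.05); sG <- c(0.02, 0.03, 0.01)
  Gam <- c(0.004, 0.012, 0.001)
  h3 <- make_harmonized(gam, rep(0.01, 3), Gam, sG)
  ratio <- Gam / gam
  w <- gam^2 / sG^2
  b0 <- sum((1 / sG^2) * gam * Gam) / sum((1 / sG^2) * gam^2)
  q_hand <- sum(w * (ratio - b0)^2)
  got <- mr_cochran_q(h3)
  expect_equal(got$q, q_hand, tolerance = 1e-12)
  expect_equal(got$df, 2L)
  expect_equal(got$pvalue, pchisq(q_hand, 2, lower.tail = FALSE))
})

test_that("scale transforms are exact linear maps and guarded", {
  est <- grsmr:::mr_estimate("ivw_fixed", 1, 0.2, 10L,
                             exposure_scale = "log_odds")
  dbl <- scale_per_doubling(est)
  expect_equal(dbl$beta, log(2))
  expect_equal(dbl$ci_high - dbl$ci_low, (est$ci_high - est$ci_low) * log(2))
  expect_equal(dbl$scale, "per_doubling")
  expect_equal(scale_per_doubling(grsmr:::mr_estimate(
    "ivw_fixed", 0, 0.2, 10L, exposure_scale = "log_odds"))$beta, 0)
  cont <- grsmr:::mr_estimate("ivw_fixed", 1, 0.2, 10L)
  expect_error(scale_per_doubling(cont), "log-odds")
  expect_error(scale_per_doubling(dbl), "per_unit")

  # OR round trip is the exp/log identity
  set.seed(2)
  for (b in rnorm(5)) {
    e <- grsmr:::mr_estimate("ivw_fixed", b, 0.1, 5L)
    expect_equal(log(to_odds_ratio(e)$or), b, tolerance = 1e-15)
  }
  expect_equal(to_odds_ratio(grsmr:::mr_estimate("ivw_fixed", 0, 0.1, 5L))$or, 1)
  expect_equal(to_odds_ratio(grsmr:::mr_estimate(
    "ivw_fixed", log(1.02), 0.1, 5L))$or, 1.02)
})

test_that("estimate rows satisfy their structural invariants", {
  h <- random_harmonized(10, slope = 0.05, noise = 0.02, seed = 9)
  rows <- mr_all(h, n_boot = 100, seed = 1)
  expect_true(all(rows$ci_low < rows$beta & rows$beta < rows$ci_high))
  expect_true(all(rows$pvalue > 0 & rows$pvalue <= 1))
  expect_s3_class(attr(rows, "heterogeneity"), "tbl_df")
})
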